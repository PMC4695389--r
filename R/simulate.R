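# Ground-truthed synthetic data for every pipeline stage.
#
# The generator emits GPCR-like repertoires evolved along known trees with
# planted gain/loss events at the motif positions, and Hill-shaped assay
# plates with Gaussian noise — so annotation, census, reconstruction and
# curve fitting can all be validated against recorded truth without any
# external data. A single integer seed drives every stage through a fixed
# splitting scheme.

# deterministic sub-seed for stage k of a run (kept below 2^31)
.split_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1e6) * 1009 + k * 104729) %% 2147483647L
}

AA20 <- setdiff(AA_ALPHABET, "X")

# substitute each unprotected site independently with probability p,
# replacing with a uniform draw from the other 19 residues
.mutate_sites <- function(chars, p, protected) {
  free <- setdiff(seq_along(chars), protected)
  hit <- free[stats::runif(length(free)) < p]
  for (i in hit) {
    chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  }
  chars
}

# protected site indices of a profile: landmark positions plus the focal
# motif positions (and any extra generic numbers)
.protected_sites <- function(profile,
                             extra = c("3.32", "5.42", "5.43")) {
  lk <- stats::setNames(profile$bw_map$index, profile$bw_map$bw)
  unique(c(profile$landmarks$index,
           unname(lk[intersect(c(extra), names(lk))])))
}

#' Simulate a pure-birth tree
#'
#' Pure-birth (Yule) tree conditioned on the requested number of tips,
#' with tips relabelled `t1..tn`.
#'
#' @param n_tips number of tips (>= 3).
#' @param seed integer seed; fixed seed gives an identical tree.
#' @param birth birth rate per lineage per unit time.
#' @return An [ape::phylo] ultrametric tree.
#' @export
simulate_tree <- function(n_tips, seed = 1, birth = 1) {
  stopifnot(n_tips >= 3)
  set.seed(.split_seed(seed, 1L))
  tree <- ape::rphylo(n_tips, birth = birth, death = 0)
  tree$tip.label <- paste0("t", seq_len(n_tips))
  tree
}

# resolve a planted-event branch: the edge leading to the MRCA of `tips`
.event_edge <- function(tree, tips) {
  node <- if (length(tips) == 1L) match(tips, tree$tip.label) else
    ape::getMRCA(tree, tips)
  e <- which(tree$edge[, 2] == node)
  if (!length(e)) stop("planted event references a non-existent branch",
                       call. = FALSE)
  e
}

#' Evolve a receptor repertoire along a tree with planted motif events
#'
#' Starting from an annotated root profile (default: the synthetic class-A
#' reference), sites outside the protected landmark/motif positions mutate
#' under a uniform replacement process; the motif positions change only
#' through planted events, which rewrite the focal residue on their branch
#' (gain writes `D`; loss writes `loss_to`, `N` by default to mirror a
#' charge-neutralizing change, `A` also supported). Because the generator
#' introduces no indels, every tip shares the root's residue layout, so
#' each tip's true generic-number map and motif category are recorded
#' exactly.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param divergence expected per-site substitution probability from root
#'   to tip (branch-wise probabilities scale with branch length relative
#'   to the maximum root-to-tip depth).
#' @param events list of planted events, each a list with `character`
#'   (`"X"` or `"Y"`), `type` (`"gain"` or `"loss"`), and `tips` (tip
#'   labels whose MRCA stem carries the event).
#' @param root_profile a `reference_profile` used as root sequence and
#'   truth layout.
#' @param root_states named logical vector `c(X = , Y = )` giving the root
#'   motif states; defaults are read from the root sequence.
#' @param seed integer seed.
#' @param group,species metadata stamped on the emitted records.
#' @param loss_to residue written by a loss event (`"N"` or `"A"`).
#' @return A list: `receptors` (a `receptor_set`), `history` (planted
#'   truth: `tree`, `events` with edge ids, `tip_states`,
#'   `tip_categories`, `truth_map`), and `tree`.
#' @export
evolve_repertoire <- function(tree, divergence = 0.2, events = list(),
                              root_profile = synthetic_reference_profile(),
                              root_states = NULL, seed = 1,
                              group = "synthetic repertoire",
                              species = "synthetic", loss_to = "N") {
  validate_tree(tree)
  stopifnot(loss_to %in% c("N", "A"), divergence >= 0, divergence < 1)
  set.seed(.split_seed(seed, 2L))
  lk <- stats::setNames(root_profile$bw_map$index, root_profile$bw_map$bw)
  focal <- c(X = unname(lk[["3.32"]]), Y = unname(lk[["5.42"]]))
  anchor_idx <- root_profile$landmarks$index
  if (any(focal %in% anchor_idx)) {
    stop("planted-event position coincides with a protected landmark anchor",
         call. = FALSE)
  }
  protected <- .protected_sites(root_profile)
  root_chars <- strsplit(root_profile$sequence, "")[[1]]
  if (is.null(root_states)) {
    root_states <- c(X = root_chars[focal[["X"]]] == "D",
                     Y = root_chars[focal[["Y"]]] == "D")
  }
  # root sequence consistent with the requested root states
  root_chars[focal[["X"]]] <- if (root_states[["X"]]) "D" else loss_to
  root_chars[focal[["Y"]]] <- if (root_states[["Y"]]) "D" else "S"

  ev_edges <- integer(0)
  ev_tab <- NULL
  for (ev in events) {
    stopifnot(ev$character %in% c("X", "Y"), ev$type %in% c("gain", "loss"))
    e <- .event_edge(tree, ev$tips)
    ev_edges <- c(ev_edges, e)
    ev_tab <- rbind(ev_tab, data.frame(character = ev$character,
                                       type = ev$type, edge = e,
                                       parent = tree$edge[e, 1],
                                       child = tree$edge[e, 2]))
  }

  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  depth <- max(ape::node.depth.edgelength(tree))
  seqs <- vector("list", nn)
  states <- matrix(NA, nn, 2, dimnames = list(NULL, c("X", "Y")))
  root <- n + 1L
  seqs[[root]] <- root_chars
  states[root, ] <- root_states[c("X", "Y")]
  pre <- ape::reorder.phylo(tree, "postorder")$edge
  pre <- pre[rev(seq_len(nrow(pre))), , drop = FALSE]
  for (k in seq_len(nrow(pre))) {
    u <- pre[k, 1]; v <- pre[k, 2]
    e <- which(tree$edge[, 1] == u & tree$edge[, 2] == v)
    len <- tree$edge.length[e]
    p_edge <- if (depth > 0 && divergence > 0)
      1 - (1 - divergence)^(len / depth) else 0
    ch <- .mutate_sites(seqs[[u]], p_edge, protected)
    st <- states[u, ]
    if (!is.null(ev_tab)) {
      for (r in which(ev_tab$edge == e)) {
        cc <- ev_tab$character[r]
        gain <- ev_tab$type[r] == "gain"
        st[cc] <- gain
        ch[focal[[cc]]] <- if (gain) "D" else loss_to
      }
    }
    seqs[[v]] <- ch
    states[v, ] <- st
  }
  tip_states <- states[seq_len(n), , drop = FALSE]
  rownames(tip_states) <- tree$tip.label
  cat_of <- function(x, y) if (x && y) "both" else if (x) "X_only" else
    if (y) "Y_only" else "neither"
  tip_categories <- stats::setNames(
    mapply(cat_of, tip_states[, "X"], tip_states[, "Y"]), tree$tip.label)
  receptors <- receptor_set(
    id = tree$tip.label,
    sequence = vapply(seqs[seq_len(n)], paste, character(1), collapse = ""),
    species = species, group = group,
    provenance = sprintf("evolve_repertoire(seed = %d)", seed)
  )
  history <- list(tree = tree, events = ev_tab, tip_states = tip_states,
                  tip_categories = tip_categories,
                  truth_map = root_profile$bw_map,
                  root_states = root_states)
  list(receptors = receptors, history = history, tree = tree)
}

#' Simulate the two-step gain-then-loss scenario
#'
#' Builds a repertoire whose history mirrors the proposed origin of
#' non-classical amine recognition: an outgroup and a basal clade keep the
#' canonical helix-III aspartate only (X_only); a planted Y gain on the
#' stem of a derived group creates an intermediate grade carrying both
#' aspartates; a nested X loss then creates a large derived clade with the
#' helix-V aspartate only. The returned truth names the focal clade tips
#' and the expected verdict (`two_step_gain_then_loss`).
#'
#' @param seed integer seed.
#' @param n_clade1,n_grade,n_clade3 tip counts of the basal clade, the
#'   intermediate grade and the derived clade.
#' @param divergence root-to-tip per-site substitution probability.
#' @return As [evolve_repertoire()], plus `outgroup` (tip label),
#'   `focal_clade` (tip labels of the derived clade) and
#'   `expected_verdict`.
#' @export
simulate_two_step <- function(seed = 1, n_clade1 = 4, n_grade = 3,
                              n_clade3 = 8, divergence = 0.2) {
  stopifnot(n_clade1 >= 2, n_grade >= 2, n_clade3 >= 2)
  # assemble newick: (OG, (cladeI, (grade, cladeIII)));
  frag <- function(n, k, label0) {
    t <- simulate_tree(n, seed = .split_seed(seed, k))
    t$edge.length <- t$edge.length / max(ape::node.depth.edgelength(t)) * 0.3
    t$tip.label <- sprintf("%s%d", label0, seq_len(n))
    sub("[;]$", "", ape::write.tree(t))
  }
  txt <- sprintf("(OG:1.0,(%s:0.2,(%s:0.2,%s:0.2):0.15):0.15);",
                 frag(n_clade1, 11L, "c1_"), frag(n_grade, 12L, "g_"),
                 frag(n_clade3, 13L, "c3_"))
  tree <- ape::read.tree(text = txt)
  grade_tips <- sprintf("g_%d", seq_len(n_grade))
  clade3_tips <- sprintf("c3_%d", seq_len(n_clade3))
  events <- list(
    list(character = "Y", type = "gain", tips = c(grade_tips, clade3_tips)),
    list(character = "X", type = "loss", tips = clade3_tips)
  )
  out <- evolve_repertoire(tree, divergence = divergence, events = events,
                           root_states = c(X = TRUE, Y = FALSE),
                           seed = seed, group = "two-step scenario")
  out$outgroup <- "OG"
  out$focal_clade <- clade3_tips
  out$expected_verdict <- "two_step_gain_then_loss"
  out
}

#' Build a repertoire with exact planted census counts
#'
#' Emits one record per requested receptor, each derived from the root
#' profile with the motif positions set according to its planted category
#' and free sites mutated independently at the given divergence. The true
#' census of the emitted set equals the request by construction, which
#' makes it the end-to-end golden fixture for annotate -> classify ->
#' census.
#'
#' @param counts data frame with columns `group`, `category` (one of
#'   `X_only`, `Y_only`, `both`, `neither`) and `n`; optional columns
#'   `clade` (clade label stamped on the records), `x_state` (residue at
#'   3.32 for categories without X: `"N"` default, `"E"` plants the
#'   conservative glutamate variant, which only counts as the motif under
#'   `acid_mode = "anion_DE"`; categories with X always carry `"D"`), and
#'   `y_at` (`"5.42"` default or `"5.43"` for receptors carrying the
#'   helix-V acid one turn later).
#' @param divergence per-site substitution probability applied to free
#'   sites of each record.
#' @param seed integer seed.
#' @return A list: `receptors` (a `receptor_set` with group/clade
#'   metadata), `truth` (per-receptor planted assignments) and `expected`
#'   (the planted per-group category table).
#' @export
make_census_fixture <- function(counts, divergence = 0.1, seed = 1) {
  stopifnot(is.data.frame(counts),
            all(c("group", "category", "n") %in% names(counts)))
  if (any(counts$n < 0)) stop("infeasible (negative) counts", call. = FALSE)
  if (!all(counts$category %in% CENSUS_CATEGORIES)) {
    stop("unknown category in counts", call. = FALSE)
  }
  if (is.null(counts$clade)) counts$clade <- NA_character_
  if (is.null(counts$x_state)) counts$x_state <- "D"
  if (is.null(counts$y_at)) counts$y_at <- "5.42"
  profile <- synthetic_reference_profile()
  lk <- stats::setNames(profile$bw_map$index, profile$bw_map$bw)
  protected <- .protected_sites(profile)
  base <- strsplit(profile$sequence, "")[[1]]
  set.seed(.split_seed(seed, 3L))
  ids <- character(0); seqs <- character(0)
  groups <- character(0); clades <- character(0)
  truth <- NULL
  for (r in seq_len(nrow(counts))) {
    nr <- counts$n[r]
    if (nr == 0) next
    has_x <- counts$category[r] %in% c("X_only", "both")
    has_y <- counts$category[r] %in% c("Y_only", "both")
    for (i in seq_len(nr)) {
      ch <- .mutate_sites(base, divergence, protected)
      # category counts are stated under asp_only: X rows carry D; rows
      # without X carry N, or the conservative E when x_state = "E"
      ch[lk[["3.32"]]] <- if (has_x) "D" else
        if (counts$x_state[r] == "E") "E" else "N"
      if (counts$y_at[r] == "5.43") {
        ch[lk[["5.43"]]] <- if (has_y) "D" else "T"
        ch[lk[["5.42"]]] <- "A"
      } else {
        ch[lk[["5.42"]]] <- if (has_y) "D" else "S"
        ch[lk[["5.43"]]] <- "S"
      }
      id <- sprintf("%s_%s_b%d_%d", gsub("[^A-Za-z0-9]", "", counts$group[r]),
                    counts$category[r], r, i)
      ids <- c(ids, id); seqs <- c(seqs, paste(ch, collapse = ""))
      groups <- c(groups, counts$group[r])
      clades <- c(clades, counts$clade[r])
      truth <- rbind(truth, data.frame(id = id, group = counts$group[r],
                                       clade = counts$clade[r],
                                       category = counts$category[r],
                                       x_state = counts$x_state[r],
                                       y_at = counts$y_at[r]))
    }
  }
  receptors <- receptor_set(id = ids, sequence = seqs, group = groups,
                            clade = clades,
                            provenance = sprintf(
                              "make_census_fixture(seed = %d)", seed))
  expected <- stats::aggregate(n ~ group + category, data = counts, FUN = sum)
  list(receptors = receptors, truth = truth, expected = expected)
}

#' Simulate reporter-assay dose-response plates
#'
#' Responses follow the 4PL model plus additive Gaussian noise with
#' standard deviation `noise_frac * top`; no-receptor control wells sit at
#' the bottom level with the same noise.
#'
#' @param truth data frame with columns `receptor`, `ligand`, `bottom`,
#'   `top`, `ec50`, `hill` (one row per curve to simulate).
#' @param concentrations ascending positive molar grid (default 8
#'   half-log-spaced points from 10 nM to 1 mM, bracketing the micromolar
#'   potencies typical of reporter assays).
#' @param replicates measurements per concentration.
#' @param noise_frac noise sd as a fraction of `top`.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return A list: `data` (data frame `receptor`, `ligand`,
#'   `concentration`, `replicate`, `response`, `is_control`), `curves`
#'   (named list of [dose_response_curve()] with controls attached) and
#'   `truth`.
#' @export
simulate_assay <- function(truth,
                           concentrations = 10^seq(-8, -3, length.out = 8),
                           replicates = 3, noise_frac = 0.05, seed = 1) {
  stopifnot(all(c("receptor", "ligand", "bottom", "top", "ec50", "hill")
                %in% names(truth)),
            all(concentrations > 0), !is.unsorted(concentrations),
            noise_frac >= 0)
  set.seed(.split_seed(seed, 4L))
  rows <- list()
  curves <- list()
  for (r in seq_len(nrow(truth))) {
    tr <- truth[r, ]
    sd_r <- noise_frac * tr$top
    mu <- hill_response(rep(concentrations, each = replicates),
                        tr$bottom, tr$top, tr$ec50, tr$hill)
    resp <- mu + stats::rnorm(length(mu), 0, sd_r)
    ctrl_resp <- tr$bottom + stats::rnorm(length(concentrations) * replicates,
                                          0, sd_r)
    conc_rep <- rep(concentrations, each = replicates)
    repl <- rep(seq_len(replicates), times = length(concentrations))
    rows[[length(rows) + 1L]] <- rbind(
      data.frame(receptor = tr$receptor, ligand = tr$ligand,
                 concentration = conc_rep, replicate = repl,
                 response = resp, is_control = FALSE),
      data.frame(receptor = NA_character_, ligand = tr$ligand,
                 concentration = conc_rep, replicate = repl,
                 response = ctrl_resp, is_control = TRUE)
    )
    ctrl <- data.frame(concentration = conc_rep, response = ctrl_resp)
    curves[[paste(tr$receptor, tr$ligand, sep = "/")]] <-
      dose_response_curve(tr$receptor, tr$ligand, conc_rep, resp,
                          replicate = repl, control = ctrl)
  }
  list(data = do.call(rbind, rows), curves = curves, truth = truth)
}

#' Synthetic worked-example receptor mirroring a diamine receptor layout
#'
#' Builds a synthetic receptor whose residue layout reproduces the indices
#' of the canonical zebrafish diamine-receptor worked example: aspartates
#' at residue 112 (3.32) and 202 (5.42), threonine 203 (5.43), serine 199
#' (5.39) and serine 276 (6.55). The sequence is a stand-in constructed
#' from the synthetic reference architecture (longer loops, moderate TM
#' divergence), not the real receptor.
#'
#' @return A list: `sequence`, `truth` (data frame `bw`, `index`,
#'   `residue` for the five worked-example positions) and `id`.
#' @export
synthetic_taar13c_like <- function() {
  loops <- c(.loop_seq(30, 8L), .loop_seq(5, 9L), .loop_seq(8, 10L),
             .loop_seq(10, 11L), .loop_seq(25, 12L), .loop_seq(23, 13L),
             .loop_seq(5, 14L), .loop_seq(20, 15L))
  helices <- .helix_seqs
  # plant the diamine-receptor pocket: D5.42 (offset 8 of TM5), T5.43 (9),
  # S5.39 (5), S6.55 (offset 26 of TM6); 3.32 is already D in the scaffold
  h5 <- strsplit(helices[5], "")[[1]]
  h5[5] <- "S"; h5[8] <- "D"; h5[9] <- "T"
  helices[5] <- paste(h5, collapse = "")
  h6 <- strsplit(helices[6], "")[[1]]
  h6[26] <- "S"
  helices[6] <- paste(h6, collapse = "")
  parts <- .assemble_profile(helices = helices, loops = loops)
  prof <- build_reference(parts$sequence, parts$bw_map)
  # moderate background divergence away from landmarks and pocket positions
  protected <- .protected_sites(prof, extra = c("3.32", "5.39", "5.42",
                                                "5.43", "6.55"))
  set.seed(.split_seed(13L, 5L))
  ch <- .mutate_sites(strsplit(prof$sequence, "")[[1]], 0.2, protected)
  seqn <- paste(ch, collapse = "")
  lk <- stats::setNames(prof$bw_map$index, prof$bw_map$bw)
  bw <- c("3.32", "5.39", "5.42", "5.43", "6.55")
  truth <- data.frame(bw = bw, index = unname(lk[bw]),
                      residue = ch[unname(lk[bw])])
  list(id = "synthetic_taar13c_like", sequence = seqn, truth = truth)
}
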