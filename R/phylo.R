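# Distance trees and ancestral motif states.
#
# The tree layer is deliberately desk-scale: pairwise-alignment distances
# and neighbor joining give a reproducible topology in seconds, and
# externally computed maximum-likelihood trees can be imported via
# read_newick() and used interchangeably. Ancestral presence/absence of the
# two motif characters is reconstructed by unit-cost parsimony with full
# minimal state sets, so transition orderings are only called firm when
# they hold under every most-parsimonious reconstruction.

#' Pairwise distance matrix from a receptor set
#'
#' Distances come from pairwise global alignments: the p-distance is
#' mismatches over compared columns, where a column is compared when both
#' sequences carry a residue (single-gap columns are not compared; columns
#' containing the ambiguity letter `X` are also skipped). The Poisson
#' correction `-ln(1 - p)` converts p-distances to expected substitutions
#' per site under a uniform replacement process.
#'
#' @param x a `receptor_set` with at least 3 receptors.
#' @param params an [align_params()] list.
#' @param correction `"p"` (raw proportion) or `"poisson"`.
#' @return A square symmetric numeric matrix with zero diagonal, receptor
#'   ids as dimnames and a `correction` attribute.
#' @export
compute_distances <- function(x, params = align_params(),
                              correction = c("p", "poisson")) {
  stopifnot(inherits(x, "receptor_set"))
  correction <- match.arg(correction)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 receptors", call. = FALSE)
  D <- matrix(0, n, n, dimnames = list(x$id, x$id))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      al <- .align_strings(x$sequence[i], x$sequence[j], params)
      a <- strsplit(al$a, "")[[1]]
      b <- strsplit(al$b, "")[[1]]
      cmp <- a != "-" & b != "-" & a != "X" & b != "X"
      if (sum(cmp) == 0L) {
        stop(sprintf("no comparable aligned columns between '%s' and '%s'",
                     x$id[i], x$id[j]), call. = FALSE)
      }
      p <- sum(a[cmp] != b[cmp]) / sum(cmp)
      if (correction == "poisson") {
        if (p >= 1) {
          stop(sprintf("saturated distance (p >= 1) between '%s' and '%s'",
                       x$id[i], x$id[j]), call. = FALSE)
        }
        p <- -log(1 - p)
      }
      D[i, j] <- D[j, i] <- p
    }
  }
  attr(D, "correction") <- correction
  D
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration with two contracts that make results
#' reproducible: ties in the Q criterion are broken by joining the pair
#' whose clusters carry the lexicographically smallest tip labels, and
#' negative branch lengths (possible on non-additive input) are clamped to
#' zero with a warning. On an additive matrix the algorithm returns the
#' generating topology and branch lengths exactly.
#'
#' @param D square symmetric distance matrix with labelled dimnames.
#' @return An unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  labels <- rownames(D)
  if (is.null(labels)) stop("distance matrix must have labelled dimnames",
                            call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(D < 0) || any(abs(diag(D)) > 1e-12)) {
    stop("distance matrix must be non-negative with zero diagonal",
         call. = FALSE)
  }
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa", call. = FALSE)
  # each active cluster: newick fragment + smallest contained tip label
  newick <- labels
  minlab <- labels
  clamped <- FALSE
  fmt <- function(v) sprintf("%.12g", v)
  while (n > 3L) {
    r <- rowSums(D)
    best <- NULL
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        q <- (n - 2) * D[i, j] - r[i] - r[j]
        lab <- sort(c(minlab[i], minlab[j]))
        if (is.null(best) || q < best$q - 1e-12 ||
            (abs(q - best$q) <= 1e-12 &&
             (lab[1] < best$lab[1] ||
              (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
          best <- list(q = q, i = i, j = j, lab = lab)
        }
      }
    }
    i <- best$i; j <- best$j
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    if (vi < 0 || vj < 0) { clamped <- TRUE; vi <- max(vi, 0); vj <- max(vj, 0) }
    new_frag <- sprintf("(%s:%s,%s:%s)", newick[i], fmt(vi),
                        newick[j], fmt(vj))
    new_min <- min(minlab[i], minlab[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- matrix(0, n - 1L, n - 1L)
    D2[seq_along(keep), seq_along(keep)] <- D[keep, keep]
    D2[n - 1L, seq_along(keep)] <- D2[seq_along(keep), n - 1L] <- dk[keep]
    D <- D2
    newick <- c(newick[keep], new_frag)
    minlab <- c(minlab[keep], new_min)
    n <- n - 1L
  }
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  if (min(va, vb, vc) < 0) clamped <- TRUE
  v <- pmax(c(va, vb, vc), 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", newick[1], fmt(v[1]),
                 newick[2], fmt(v[2]), newick[3], fmt(v[3]))
  tree <- ape::read.tree(text = txt)
  if (clamped) {
    warning("negative branch length(s) clamped to 0", call. = FALSE)
    attr(tree, "clamped") <- TRUE
  }
  tree
}

# --- unit-cost parsimony (Sankoff) ----------------------------------------

# inside/outside DP for one binary character; states coded 1 = "0", 2 = "1"
.sankoff_binary <- function(tree, tip_states) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  nn <- n + m
  INF <- 1e9
  cost <- matrix(INF, nn, 2)
  for (i in seq_len(n)) {
    s <- tip_states[tree$tip.label[i]]
    cost[i, ] <- if (is.na(s) || s == "?") c(0, 0) else
      if (s == "0") c(0, INF) else c(INF, 0)
  }
  po <- ape::reorder.phylo(tree, "postorder")
  children <- split(po$edge[, 2], po$edge[, 1])
  for (v in unique(po$edge[, 1])) cost[v, ] <- 0
  # postorder guarantees children before parents
  for (k in seq_len(nrow(po$edge))) {
    u <- po$edge[k, 1]; w <- po$edge[k, 2]
    cost[u, 1] <- cost[u, 1] + min(cost[w, 1], cost[w, 2] + 1)
    cost[u, 2] <- cost[u, 2] + min(cost[w, 2], cost[w, 1] + 1)
  }
  root <- n + 1L
  total <- min(cost[root, ])
  # outside pass (preorder): o[v,s] over the rest of the tree
  outside <- matrix(INF, nn, 2)
  outside[root, ] <- 0
  pre <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
  # sibling contribution: for child v of u, cost of u's other subtrees given
  # state t at u equals sum over siblings w of min_r(cost[w,r] + (t != r))
  sib_sum <- function(u, v, t) {
    s <- 0
    for (w in children[[as.character(u)]]) {
      if (w == v) next
      s <- s + min(cost[w, t], cost[w, 3 - t] + 1)
    }
    s
  }
  for (k in seq_len(nrow(pre))) {
    u <- pre[k, 1]; v <- pre[k, 2]
    for (s in 1:2) {
      outside[v, s] <- min(vapply(1:2, function(t) {
        outside[u, t] + (t != s) + sib_sum(u, v, t)
      }, numeric(1)))
    }
  }
  # minimal state sets per node
  sets <- matrix(FALSE, nn, 2, dimnames = list(NULL, c("0", "1")))
  for (v in seq_len(nn)) {
    for (s in 1:2) sets[v, s] <- (cost[v, s] + outside[v, s]) <= total + 1e-9
  }
  # per-edge change analysis
  ne <- nrow(tree$edge)
  edge_tab <- data.frame(edge = seq_len(ne), parent = tree$edge[, 1],
                         child = tree$edge[, 2], can_gain = FALSE,
                         can_loss = FALSE, can_same = FALSE)
  for (k in seq_len(ne)) {
    u <- tree$edge[k, 1]; v <- tree$edge[k, 2]
    tot <- function(a, b) outside[u, a] + (a != b) + cost[v, b] + sib_sum(u, v, a)
    edge_tab$can_gain[k] <- tot(1, 2) <= total + 1e-9
    edge_tab$can_loss[k] <- tot(2, 1) <= total + 1e-9
    edge_tab$can_same[k] <- min(tot(1, 1), tot(2, 2)) <= total + 1e-9
  }
  list(min_changes = as.integer(total), sets = sets, edges = edge_tab)
}

#' Ancestral reconstruction of the motif characters by parsimony
#'
#' Unit-cost parsimony on a rooted tree for the binary characters X (anion
#' at 3.32) and Y (anion at 5.42/5.43). Tips with `?` contribute the full
#' state set. The reconstruction reports, per node and character, the set
#' of states occurring in at least one most-parsimonious reconstruction,
#' the parsimony minimum change count, and per-branch events: an event is
#' `firm` when the branch changes state in every minimal reconstruction
#' and `possible` when it changes in some but not all.
#'
#' @param tree an [ape::phylo] tree; rooted, or rootable via `outgroup`.
#' @param chars a [character_matrix()] (columns `id`, `X`, `Y`), or any
#'   data frame with an `id` column and binary character columns.
#' @param outgroup optional tip label(s) used to root the tree.
#' @return An object of class `ancestral_reconstruction`: `tree` (the
#'   rooted binary tree used; node numbers refer to it), `min_changes`,
#'   `state_sets` (per character, nodes x states logical matrix), and
#'   `events` (data frame: character, edge, parent, child, type, direction).
#' @export
fitch_parsimony <- function(tree, chars, outgroup = NULL) {
  validate_tree(tree)
  stopifnot(is.data.frame(chars), "id" %in% names(chars))
  if (!is.null(outgroup)) {
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  if (!ape::is.rooted(tree)) {
    stop("tree must be rooted (supply an outgroup)", call. = FALSE)
  }
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  missing_tips <- setdiff(chars$id, tree$tip.label)
  if (length(missing_tips)) {
    stop("tip(s) in character matrix missing from tree: ",
         paste(missing_tips, collapse = ", "), call. = FALSE)
  }
  char_cols <- setdiff(names(chars), "id")
  min_changes <- integer(0)
  state_sets <- list()
  events <- list()
  for (cc in char_cols) {
    st <- stats::setNames(as.character(chars[[cc]]), chars$id)
    res <- .sankoff_binary(tree, st)
    min_changes[cc] <- res$min_changes
    state_sets[[cc]] <- res$sets
    e <- res$edges
    chg <- e$can_gain | e$can_loss
    for (k in which(chg)) {
      type <- if (!e$can_same[k]) "firm" else "possible"
      direction <- if (e$can_gain[k] && e$can_loss[k]) "ambiguous" else
        if (e$can_gain[k]) "gain" else "loss"
      events[[length(events) + 1L]] <- data.frame(
        character = cc, edge = e$edge[k], parent = e$parent[k],
        child = e$child[k], type = type, direction = direction,
        stringsAsFactors = FALSE
      )
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(character = character(0), edge = integer(0),
               parent = integer(0), child = integer(0),
               type = character(0), direction = character(0))
  structure(list(tree = tree, min_changes = min_changes,
                 state_sets = state_sets, events = events),
            class = "ancestral_reconstruction")
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat("Ancestral reconstruction (unit-cost parsimony)\n")
  for (cc in names(x$min_changes)) {
    ev <- x$events[x$events$character == cc, , drop = FALSE]
    cat(sprintf("  character %s: %d change(s), %d firm / %d possible event(s)\n",
                cc, x$min_changes[[cc]], sum(ev$type == "firm"),
                sum(ev$type == "possible")))
  }
  invisible(x)
}

#' Order motif transitions on an ancestor-to-clade path
#'
#' Tests the two-step scenario — gain of the helix-V anion (Y) before loss
#' of the helix-III anion (X) — on the path from a designated ancestral
#' node to the ancestor of a focal clade. Events are ordered rootward to
#' tipward. The verdict is `two_step_gain_then_loss` only when a firm Y
#' gain strictly precedes a firm X loss on the path; orderings that hold
#' under only some minimal reconstructions are reported as
#' `simultaneous_ambiguous`, never silently resolved.
#'
#' @param recon an [fitch_parsimony()] reconstruction.
#' @param focal_clade tip labels of the focal clade (its MRCA is the path
#'   endpoint), or a single node number of `recon$tree`.
#' @param ancestor node number of the designated ancestor; default the root.
#' @return An object of class `transition_narrative`: ordered `events` on
#'   the path and a `verdict` in `two_step_gain_then_loss`,
#'   `loss_then_gain`, `simultaneous_ambiguous`, `other`.
#' @export
infer_transition_order <- function(recon, focal_clade, ancestor = NULL) {
  stopifnot(inherits(recon, "ancestral_reconstruction"))
  tree <- recon$tree
  n <- length(tree$tip.label)
  if (is.character(focal_clade)) {
    miss <- setdiff(focal_clade, tree$tip.label)
    if (length(miss)) stop("unknown tip(s): ", paste(miss, collapse = ", "),
                           call. = FALSE)
    focal <- if (length(focal_clade) == 1L) match(focal_clade, tree$tip.label)
      else ape::getMRCA(tree, focal_clade)
  } else {
    focal <- as.integer(focal_clade)
  }
  if (is.null(ancestor)) ancestor <- n + 1L
  path_nodes <- ape::nodepath(tree, ancestor, focal)
  if (path_nodes[1] != ancestor) {
    stop("focal clade is not a descendant of the designated ancestor",
         call. = FALSE)
  }
  # edges along the path, rootward to tipward
  edge_ids <- integer(0)
  for (k in seq_len(length(path_nodes) - 1L)) {
    e <- which(tree$edge[, 1] == path_nodes[k] &
                 tree$edge[, 2] == path_nodes[k + 1L])
    if (!length(e)) stop("focal clade is not a descendant of the ancestor",
                         call. = FALSE)
    edge_ids <- c(edge_ids, e)
  }
  ev <- recon$events[recon$events$edge %in% edge_ids, , drop = FALSE]
  if (nrow(ev)) {
    ev$step <- match(ev$edge, edge_ids)
    ev <- ev[order(ev$step), , drop = FALSE]
  } else {
    ev$step <- integer(0)
  }
  firm <- ev[ev$type == "firm", , drop = FALSE]
  y_gain <- firm$step[firm$character == "Y" & firm$direction == "gain"]
  x_loss <- firm$step[firm$character == "X" & firm$direction == "loss"]
  verdict <- if (length(y_gain) && length(x_loss) &&
                 min(y_gain) < min(x_loss)) {
    "two_step_gain_then_loss"
  } else if (length(y_gain) && length(x_loss) &&
             min(x_loss) < min(y_gain)) {
    "loss_then_gain"
  } else if (length(y_gain) && length(x_loss)) {
    "simultaneous_ambiguous"  # same branch: order undecidable
  } else if (any(ev$character == "Y" & ev$direction %in% c("gain", "ambiguous")) &&
             any(ev$character == "X" & ev$direction %in% c("loss", "ambiguous"))) {
    "simultaneous_ambiguous"  # only holds under some minimal resolutions
  } else {
    "other"
  }
  structure(list(events = ev, verdict = verdict, ancestor = ancestor,
                 focal = focal),
            class = "transition_narrative")
}

#' @export
print.transition_narrative <- function(x, ...) {
  cat("Transition narrative:", x$verdict, "\n")
  if (nrow(x$events)) {
    print.data.frame(x$events, row.names = FALSE)
  } else {
    cat("  no state changes on the designated path\n")
  }
  invisible(x)
}

#' Label clades from seed taxa
#'
#' Each clade is the smallest subtree (MRCA span) containing its seed tips;
#' tips outside every span are labelled `"unassigned"`. Overlapping spans
#' are a clade conflict and raise an error.
#'
#' @param tree an [ape::phylo] tree.
#' @param seed_taxa named list: clade label -> character vector of tip ids.
#' @return Named character vector: tip id -> clade label.
#' @export
label_clades <- function(tree, seed_taxa) {
  validate_tree(tree)
  stopifnot(is.list(seed_taxa), !is.null(names(seed_taxa)))
  spans <- lapply(seed_taxa, function(seeds) {
    miss <- setdiff(seeds, tree$tip.label)
    if (length(miss)) stop("seed tip(s) not in tree: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    if (length(seeds) == 1L) return(seeds)
    node <- ape::getMRCA(tree, seeds)
    ape::extract.clade(tree, node)$tip.label
  })
  cl_names <- names(spans)
  for (i in seq_along(spans)) {
    for (j in seq_along(spans)) {
      if (i < j && length(intersect(spans[[i]], spans[[j]]))) {
        stop(sprintf("clade conflict: spans of '%s' and '%s' overlap",
                     cl_names[i], cl_names[j]), call. = FALSE)
      }
    }
  }
  out <- stats::setNames(rep("unassigned", length(tree$tip.label)),
                         tree$tip.label)
  for (cl in cl_names) out[spans[[cl]]] <- cl
  out
}
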