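# Shared fixtures and independent oracles.

# one reference profile per test run
.ref <- synthetic_reference_profile()

# random unrooted binary tree with positive branch lengths; its cophenetic
# matrix is additive by construction (path-metric oracle for NJ)
random_additive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  ape::unroot(tr)
}

# random rooted binary tree for parsimony tests
random_rooted_tree <- function(n, seed) {
  set.seed(seed)
  ape::rtree(n)
}

# Brute-force parsimony oracle for one binary character on a rooted binary
# tree: enumerates every assignment of {0,1} to internal nodes (and to tips
# scored '?'), counts state changes over edges, and reports the minimum,
# the per-node states seen in at least one minimal labeling, and which
# edges change in every / at least one minimal labeling.
brute_parsimony <- function(tree, tip_states) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  nn <- n + m
  fixed <- rep(NA_integer_, nn)
  for (i in seq_len(n)) {
    s <- tip_states[[tree$tip.label[i]]]
    if (!is.na(s) && s != "?") fixed[i] <- as.integer(s)
  }
  free <- which(is.na(fixed))
  k <- length(free)
  best <- Inf
  sets <- matrix(FALSE, nn, 2)
  can_change <- must_change <- rep(NA, nrow(tree$edge))
  for (code in 0:(2^k - 1)) {
    st <- fixed
    if (k > 0) st[free] <- bitwAnd(bitwShiftR(code, seq_len(k) - 1L), 1L)
    chg <- st[tree$edge[, 1]] != st[tree$edge[, 2]]
    cost <- sum(chg)
    if (cost < best) {
      best <- cost
      sets[] <- FALSE
      can_change[] <- FALSE
      must_change[] <- TRUE
    }
    if (cost == best) {
      sets[cbind(seq_len(nn), st + 1L)] <- TRUE
      can_change <- can_change | chg
      must_change <- must_change & chg
    }
  }
  colnames(sets) <- c("0", "1")
  list(min = best, sets = sets, can_change = can_change,
       must_change = must_change)
}

# planted category counts mirroring a mixed vertebrate TAAR survey:
# a large fish repertoire dominated by helix-V-only receptors, plus small
# mammalian sets that keep the helix-III aspartate (two per species with
# the acid at 5.43, and two rodent receptors with Glu3.32)
paper_shaped_counts <- function() {
  data.frame(
    group = c(rep("zebrafish TAAR", 5), rep("mouse TAAR", 3),
              rep("human TAAR", 2)),
    clade = c("I", "intermediate", "III", "III", "III",
              NA, NA, NA, NA, NA),
    category = c("X_only", "both", "both", "Y_only", "neither",
                 "X_only", "both", "neither", "X_only", "both"),
    n = c(20, 5, 2, 84, 1, 11, 2, 2, 4, 2),
    x_state = c(rep("D", 5), "D", "D", "E", "D", "D"),
    y_at = c(rep("5.42", 5), "5.42", "5.43", "5.42", "5.42", "5.43"),
    stringsAsFactors = FALSE
  )
}
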