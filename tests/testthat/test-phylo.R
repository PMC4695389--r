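test_that("p-distances and Poisson correction follow the stated formulas", {
  base <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 5), collapse = "")  # 100 aa
  ch <- strsplit(base, "")[[1]]
  ch[1] <- if (ch[1] == "A") "G" else "A"
  one_diff <- paste(ch, collapse = "")
  ch10 <- strsplit(base, "")[[1]]
  idx <- seq(5, 95, by = 10)
  ch10[idx] <- ifelse(ch10[idx] == "A", "G", "A")
  ten_diff <- paste(ch10, collapse = "")
  rs <- receptor_set(id = c("a", "b", "c", "d"),
                     sequence = c(base, base, one_diff, ten_diff))
  D <- compute_distances(rs, correction = "p")
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 0.01)
  expect_equal(D["a", "d"], 0.10)
  Dp <- compute_distances(rs, correction = "poisson")
  expect_equal(Dp["a", "d"], -log(0.9))

  # maximally dissimilar sequences align without comparable columns
  sat <- receptor_set(id = c("x", "y", "z"),
                      sequence = c(strrep("A", 100), strrep("Y", 100),
                                   strrep("A", 100)))
  expect_error(compute_distances(sat, correction = "poisson"),
               "comparable.*x.*y")
})

test_that("3-taxon NJ uses the closed-form branch lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  expect_equal(ape::Ntip(tr), 3)
  len <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[["A"]], (3 + 4 - 5) / 2)
  expect_equal(len[["B"]], (3 + 5 - 4) / 2)
  expect_equal(len[["C"]], (4 + 5 - 3) / 2)
})

test_that("NJ recovers additive matrices exactly", {
  for (s in 1:10) {
    n <- sample(4:12, 1)
    tr <- random_additive_tree(n, seed = s)
    D <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(D)
    expect_equal(as.numeric(ape::dist.topo(nj, tr)), 0)
    expect_lt(max(abs(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)] -
                        D)), 1e-8)
    # independent cross-check against ape's NJ on the same matrix
    expect_equal(as.numeric(ape::dist.topo(nj, ape::nj(D))), 0)
  }
})

test_that("NJ ties are broken by lexicographically smallest labels", {
  labs <- c("E", "C", "A", "D", "B")
  D <- matrix(1, 5, 5, dimnames = list(labs, labs))
  diag(D) <- 0
  tr <- neighbor_joining(D)  # every Q ties; A-B must be joined first
  cherry_of <- function(tree, a, b) {
    ea <- tree$edge[tree$edge[, 2] == match(a, tree$tip.label), 1]
    eb <- tree$edge[tree$edge[, 2] == match(b, tree$tip.label), 1]
    ea == eb
  }
  expect_true(cherry_of(tr, "A", "B"))
})

test_that("NJ input validation and negative-length clamping", {
  D <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(D), "symmetric")
  # a non-additive matrix that forces a negative length estimate
  Dn <- matrix(c(0.000, 4.820, 1.686, 4.135,
                 4.820, 0.000, 2.643, 1.241,
                 1.686, 2.643, 0.000, 2.218,
                 4.135, 1.241, 2.218, 0.000), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  expect_warning(trn <- neighbor_joining(Dn), "clamped")
  expect_true(all(trn$edge.length >= 0))
})

test_that("parsimony equals the brute-force minimum with matching sets", {
  for (s in 1:40) {
    n <- sample(4:7, 1)
    tree <- random_rooted_tree(n, seed = 1000 + s)
    states <- sample(c("0", "1", "?"), n, replace = TRUE,
                     prob = c(0.45, 0.45, 0.1))
    chars <- data.frame(id = tree$tip.label, X = states)
    rec <- fitch_parsimony(tree, chars)
    oracle <- brute_parsimony(tree, stats::setNames(states, tree$tip.label))
    expect_equal(unname(rec$min_changes[["X"]]), oracle$min)
    expect_equal(unname(rec$state_sets$X), unname(oracle$sets))
    ev <- rec$events[rec$events$character == "X", ]
    firm <- rep(FALSE, nrow(tree$edge))
    firm[ev$edge[ev$type == "firm"]] <- TRUE
    possible <- rep(FALSE, nrow(tree$edge))
    possible[ev$edge] <- TRUE
    expect_equal(firm, oracle$must_change)
    expect_equal(possible, oracle$can_change)
  }
})

test_that("parsimony minimum matches phangorn's count", {
  skip_if_not_installed("phangorn")
  tree <- random_rooted_tree(8, seed = 5)
  states <- sample(c("0", "1"), 8, replace = TRUE)
  rec <- fitch_parsimony(tree, data.frame(id = tree$tip.label, X = states))
  pd <- phangorn::phyDat(matrix(states, ncol = 1,
                                dimnames = list(tree$tip.label, NULL)),
                         type = "USER", levels = c("0", "1"))
  expect_equal(unname(rec$min_changes[["X"]]),
               phangorn::fitch(tree, pd))
})

test_that("reconstruction is invariant to tip input order", {
  tree <- random_rooted_tree(7, seed = 11)
  states <- c("1", "1", "0", "0", "1", "0", "?")
  chars <- data.frame(id = tree$tip.label, X = states)
  r1 <- fitch_parsimony(tree, chars)
  perm <- sample(seq_len(7))
  r2 <- fitch_parsimony(tree, chars[perm, ])
  expect_identical(r1$min_changes, r2$min_changes)
  expect_identical(r1$state_sets, r2$state_sets)
  expect_identical(r1$events, r2$events)
})

test_that("constant characters reconstruct with zero changes", {
  tree <- random_rooted_tree(5, seed = 2)
  rec <- fitch_parsimony(tree, data.frame(id = tree$tip.label,
                                          X = rep("1", 5)))
  expect_equal(unname(rec$min_changes[["X"]]), 0)
  expect_true(all(rec$state_sets$X[, "1"]))
  expect_false(any(rec$state_sets$X[, "0"]))
  expect_equal(nrow(rec$events), 0)
})

test_that("missing tips in the character matrix are an error", {
  tree <- random_rooted_tree(4, seed = 3)
  chars <- data.frame(id = c(tree$tip.label, "ghost"),
                      X = c("1", "0", "1", "0", "1"))
  expect_error(fitch_parsimony(tree, chars), "ghost")
})

test_that("the planted two-step history is called gain-then-loss", {
  ts <- simulate_two_step(seed = 4, divergence = 0)
  cats <- ts$history$tip_categories
  cm <- data.frame(id = names(cats),
                   X = ifelse(cats %in% c("X_only", "both"), "1", "0"),
                   Y = ifelse(cats %in% c("Y_only", "both"), "1", "0"))
  rec <- fitch_parsimony(ts$tree, cm, outgroup = ts$outgroup)
  nar <- infer_transition_order(rec, ts$focal_clade)
  expect_equal(nar$verdict, "two_step_gain_then_loss")
  # the firm events on the path are one Y gain then one X loss
  firm <- nar$events[nar$events$type == "firm", ]
  expect_equal(firm$character, c("Y", "X"))
  expect_equal(firm$direction, c("gain", "loss"))
})

test_that("reversed planted order is called loss-then-gain", {
  ts <- simulate_two_step(seed = 4, divergence = 0)
  grade <- grep("^g_", names(ts$history$tip_categories), value = TRUE)
  events <- list(
    list(character = "X", type = "loss",
         tips = c(grade, ts$focal_clade)),
    list(character = "Y", type = "gain", tips = ts$focal_clade)
  )
  rep2 <- evolve_repertoire(ts$tree, divergence = 0, events = events,
                            root_states = c(X = TRUE, Y = FALSE), seed = 1)
  cats <- rep2$history$tip_categories
  cm <- data.frame(id = names(cats),
                   X = ifelse(cats %in% c("X_only", "both"), "1", "0"),
                   Y = ifelse(cats %in% c("Y_only", "both"), "1", "0"))
  rec <- fitch_parsimony(ts$tree, cm, outgroup = "OG")
  expect_equal(infer_transition_order(rec, ts$focal_clade)$verdict,
               "loss_then_gain")
})

test_that("constant paths and co-localized changes are not overcalled", {
  tree <- ape::read.tree(text = "(OG:1,(B:1,C:1):1);")
  # constant states on the path: verdict "other", empty events
  rec <- fitch_parsimony(tree, data.frame(id = c("OG", "B", "C"),
                                          X = c("1", "1", "1"),
                                          Y = c("0", "0", "0")))
  nar <- infer_transition_order(rec, c("B", "C"))
  expect_equal(nar$verdict, "other")
  expect_equal(nrow(nar$events), 0)
  # X loss and Y gain forced onto the same stem: order undecidable
  rec2 <- fitch_parsimony(tree, data.frame(id = c("OG", "B", "C"),
                                           X = c("1", "0", "0"),
                                           Y = c("0", "1", "1")))
  nar2 <- infer_transition_order(rec2, c("B", "C"))
  expect_equal(nar2$verdict, "simultaneous_ambiguous")
})

test_that("clade labelling spans MRCAs and rejects conflicts", {
  tree <- ape::read.tree(text = "(((t1:1,t2:1):1,(t3:1,t4:1):1):1,(t5:1,t6:1):2);")
  lab <- label_clades(tree, list(I = c("t1", "t2"), III = c("t5", "t6")))
  expect_equal(unname(lab[c("t1", "t2")]), c("I", "I"))
  expect_equal(unname(lab[c("t5", "t6")]), c("III", "III"))
  expect_equal(unname(lab[c("t3", "t4")]), c("unassigned", "unassigned"))
  expect_error(label_clades(tree, list(I = c("t1", "t3"),
                                       II = c("t2", "t4"))),
               "conflict")
  # planted clades in the two-step repertoire are recovered
  ts <- simulate_two_step(seed = 9, divergence = 0)
  c1 <- grep("^c1_", ts$tree$tip.label, value = TRUE)
  lab2 <- label_clades(ts$tree, list(I = c1, III = ts$focal_clade))
  expect_true(all(lab2[c1] == "I"))
  expect_true(all(lab2[ts$focal_clade] == "III"))
})
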