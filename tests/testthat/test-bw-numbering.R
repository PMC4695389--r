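test_that("reference construction validates landmarks and numbering", {
  ref <- .ref
  expect_s3_class(ref, "reference_profile")
  expect_equal(nrow(ref$landmarks), 11)
  expect_true(all(mapply(
    function(obs, exp) obs %in% strsplit(exp, "|", fixed = TRUE)[[1]],
    ref$landmarks$observed, ref$landmarks$expected)))
  expect_identical(read_reference_profile(
    system.file("extdata", "reference_synthetic_class_a.tsv",
                package = "amrec"))$bw_map, ref$bw_map)

  # gap in helix-3 numbering violates the consecutive invariant
  bad_map <- ref$bw_map[ref$bw_map$bw != "3.30", ]
  expect_error(build_reference(ref$sequence, bad_map), "non-consecutive")

  # landmark residue absent at its annotated position
  seq_bad <- ref$sequence
  r350 <- ref$bw_map$index[ref$bw_map$bw == "3.50"]
  substr(seq_bad, r350, r350) <- "A"
  expect_error(build_reference(seq_bad, ref$bw_map), "3.50|DRY")
})

test_that("self-alignment is the identity and deletions give single gaps", {
  ref <- .ref
  aln <- align_to_reference(ref$sequence, ref)
  expect_identical(aln$query_aligned, ref$sequence)
  expect_false(grepl("-", aln$query_aligned, fixed = TRUE))

  # delete one residue -> exactly one 1-column gap in the query row
  del <- 150
  q <- paste0(substr(ref$sequence, 1, del - 1),
              substr(ref$sequence, del + 1, nchar(ref$sequence)))
  aln2 <- align_to_reference(q, ref)
  gaps <- gregexpr("-+", aln2$query_aligned)[[1]]
  expect_equal(length(gaps), 1)
  expect_equal(attr(gaps, "match.length"), 1)

  expect_error(align_to_reference("MDILA", ref), "100")
})

test_that("self-annotation reproduces the reference map exactly", {
  ref <- .ref
  ann <- assign_bw(ref$sequence, ref, id = "self")
  expect_identical(ann$map$index, ref$bw_map$index)
  expect_identical(ann$map$bw, ref$bw_map$bw)
  expect_length(ann$low_conf_helices, 0)
  expect_true(all(ann$landmarks$status == "found"))
  # injectivity: one generic number per residue and vice versa
  expect_false(anyDuplicated(ann$map$index) > 0)
  expect_false(anyDuplicated(ann$map$bw) > 0)
})

test_that("annotation is deterministic", {
  tl <- synthetic_taar13c_like()
  a1 <- assign_bw(tl$sequence, .ref, id = tl$id)
  a2 <- assign_bw(tl$sequence, .ref, id = tl$id)
  expect_identical(a1$map, a2$map)
  expect_identical(a1$landmarks, a2$landmarks)
})

test_that("diamine-receptor worked example maps the pocket positions", {
  tl <- synthetic_taar13c_like()
  ann <- assign_bw(tl$sequence, .ref, id = tl$id)
  expect_equal(residue_at(ann, "3.32")[c("index", "residue")],
               list(index = 112L, residue = "D"))
  expect_equal(residue_at(ann, "5.42")[c("index", "residue")],
               list(index = 202L, residue = "D"))
  expect_equal(residue_at(ann, "5.43")[c("index", "residue")],
               list(index = 203L, residue = "T"))
  expect_equal(residue_at(ann, "5.39")[c("index", "residue")],
               list(index = 199L, residue = "S"))
  expect_equal(residue_at(ann, "6.55")[c("index", "residue")],
               list(index = 276L, residue = "S"))
})

test_that("residue_at handles absent positions and malformed input", {
  ref <- .ref
  # delete the residue at 5.39 (unique context, so the optimal gap
  # placement is forced onto that column) -> position gapped
  i539 <- ref$bw_map$index[ref$bw_map$bw == "5.39"]
  q <- paste0(substr(ref$sequence, 1, i539 - 1),
              substr(ref$sequence, i539 + 1, nchar(ref$sequence)))
  ann <- assign_bw(q, ref)
  expect_equal(residue_at(ann, "5.39")$status, "absent")
  expect_true(5 %in% ann$indel_helices)
  expect_error(residue_at(ann, "8.42"), "malformed")
})

test_that("unnumberable sequences error and are excluded by annotate_set", {
  set.seed(99)
  junk <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                       150, replace = TRUE), collapse = "")
  expect_error(assign_bw(junk, .ref), "not a numberable GPCR")
  rs <- receptor_set(id = c("ok", "junk"),
                     sequence = c(.ref$sequence, junk))
  res <- annotate_set(rs, .ref)
  expect_named(res$annotations, "ok")
  expect_equal(res$excluded$id, "junk")
})

test_that("percent identity follows the aligned-columns convention", {
  expect_equal(as.numeric(pairwise_identity(.ref$sequence, .ref$sequence)),
               100)
  # 10 substitutions in a 308-residue gapless alignment
  ch <- strsplit(.ref$sequence, "")[[1]]
  idx <- seq(10, 100, by = 10)
  ch[idx] <- ifelse(ch[idx] == "A", "G", "A")
  q <- paste(ch, collapse = "")
  expect_equal(as.numeric(pairwise_identity(.ref$sequence, q)),
               100 * (308 - 10) / 308)
  expect_match(attr(pairwise_identity("MDA", "MDA"), "denominator"),
               "aligned columns")
})

test_that("planted motif positions are recovered under moderate divergence", {
  # 45% expected root-to-tip divergence outside protected windows
  ok <- 0L; total <- 0L
  for (s in 1:20) {
    tree <- simulate_tree(4, seed = s)
    rep <- evolve_repertoire(tree, divergence = 0.45, seed = s)
    lk <- stats::setNames(rep$history$truth_map$index,
                          rep$history$truth_map$bw)
    for (i in seq_len(nrow(rep$receptors))) {
      ann <- tryCatch(assign_bw(rep$receptors$sequence[i], .ref),
                      error = function(e) NULL)
      total <- total + 1L
      if (!is.null(ann) &&
          identical(residue_at(ann, "3.32")$index, unname(lk[["3.32"]])) &&
          identical(residue_at(ann, "5.42")$index, unname(lk[["5.42"]]))) {
        ok <- ok + 1L
      }
    }
  }
  expect_gte(ok / total, 0.95)
})
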