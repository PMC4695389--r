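# Ballesteros-Weinstein reference profiles.
#
# A reference profile is an annotated class-A GPCR sequence: every
# transmembrane residue carries a generic number "h.pp" (helix 1..7,
# two-digit position, x.50 = most conserved residue of helix x). Queries are
# numbered by global alignment to the reference, so the profile also records
# the landmark motifs used to verify that the alignment is trustworthy:
# DRY/DRH at 3.49-3.51, NPxxY at 7.49-7.53, and the helix prolines 5.50 and
# 6.50, plus the remaining x.50 anchors.

# expected residues at each landmark position ("|" separated alternatives)
.bw_landmarks <- function() {
  data.frame(
    name = c("N1.50", "D2.50", "DRY.D3.49", "DRY.R3.50", "DRY.Y3.51",
             "W4.50", "P5.50", "P6.50", "NPxxY.N7.49", "NPxxY.P7.50",
             "NPxxY.Y7.53"),
    bw = c("1.50", "2.50", "3.49", "3.50", "3.51",
           "4.50", "5.50", "6.50", "7.49", "7.50", "7.53"),
    expected = c("N", "D", "D|E", "R", "Y|H",
                 "W", "P", "P", "N", "P", "Y"),
    stringsAsFactors = FALSE
  )
}

# x.50 anchors used for the "numberable GPCR" decision
.bw_anchors <- c("1.50", "2.50", "3.50", "4.50", "5.50", "6.50", "7.50")

.bw_helix <- function(bw) as.integer(sub("\\..*$", "", bw))
.bw_pos <- function(bw) as.integer(sub("^.*\\.", "", bw))

#' Build and validate a Ballesteros-Weinstein reference profile
#'
#' @param sequence amino-acid string of the annotated template receptor.
#' @param bw_map data frame with integer column `index` (1-based residue
#'   index into `sequence`) and character column `bw` (generic number
#'   `"h.pp"`). Within each helix, generic numbers must increase by exactly
#'   one per annotated consecutive residue (class-A convention, no
#'   bulge/constriction corrections).
#' @return An object of class `reference_profile` with fields `sequence`,
#'   `bw_map`, `landmarks` (per-landmark index, expected and observed
#'   residue) and `helix_spans` (first/last annotated index per helix).
#' @export
build_reference <- function(sequence, bw_map) {
  sequence <- toupper(sequence)
  .check_aa(sequence, "reference")
  stopifnot(is.data.frame(bw_map), all(c("index", "bw") %in% names(bw_map)))
  bw_map <- bw_map[order(bw_map$index), c("index", "bw")]
  bw_map$index <- as.integer(bw_map$index)
  if (anyDuplicated(bw_map$index) || anyDuplicated(bw_map$bw)) {
    stop("bw_map must be injective (no duplicate indices or generic numbers)",
         call. = FALSE)
  }
  if (any(bw_map$index < 1L) || any(bw_map$index > nchar(sequence))) {
    stop("bw_map index outside the reference sequence", call. = FALSE)
  }
  helix <- .bw_helix(bw_map$bw)
  pos <- .bw_pos(bw_map$bw)
  if (any(is.na(helix)) || any(helix < 1L) || any(helix > 7L)) {
    stop("malformed generic number(s) in bw_map", call. = FALSE)
  }
  # consecutive numbering within each helix: +1 in both index and position
  for (h in sort(unique(helix))) {
    sel <- helix == h
    if (any(diff(bw_map$index[sel]) != 1L) || any(diff(pos[sel]) != 1L)) {
      stop(sprintf("non-consecutive generic numbering within helix %d", h),
           call. = FALSE)
    }
  }
  res <- strsplit(sequence, "")[[1]]
  lm <- .bw_landmarks()
  lm$index <- bw_map$index[match(lm$bw, bw_map$bw)]
  if (any(is.na(lm$index))) {
    stop("landmark position(s) missing from bw_map: ",
         paste(lm$bw[is.na(lm$index)], collapse = ", "), call. = FALSE)
  }
  lm$observed <- res[lm$index]
  ok <- mapply(function(obs, exp) obs %in% strsplit(exp, "|", fixed = TRUE)[[1]],
               lm$observed, lm$expected)
  if (any(!ok)) {
    bad <- lm$name[!ok][1]
    stop(sprintf("reference validation failed: landmark %s expects %s, found %s",
                 bad, lm$expected[!ok][1], lm$observed[!ok][1]), call. = FALSE)
  }
  spans <- do.call(rbind, lapply(sort(unique(helix)), function(h) {
    sel <- helix == h
    data.frame(helix = h, first = min(bw_map$index[sel]),
               last = max(bw_map$index[sel]))
  }))
  structure(
    list(sequence = sequence, bw_map = bw_map, landmarks = lm,
         helix_spans = spans),
    class = "reference_profile"
  )
}

#' @export
print.reference_profile <- function(x, ...) {
  cat(sprintf("BW reference profile: %d aa, %d annotated TM residues, 7 helices\n",
              nchar(x$sequence), nrow(x$bw_map)))
  cat("  landmarks verified:", paste(x$landmarks$name, collapse = " "), "\n")
  invisible(x)
}

#' Write / read a reference profile as a delimited table
#'
#' The on-disk format is a three-column TSV (`index`, `residue`, `bw`) with
#' one row per residue of the template; unannotated (loop) residues have an
#' empty `bw` field.
#'
#' @param ref a `reference_profile`.
#' @param path file path.
#' @return `write_reference_profile()` returns `path` invisibly;
#'   `read_reference_profile()` returns a `reference_profile`.
#' @export
write_reference_profile <- function(ref, path) {
  stopifnot(inherits(ref, "reference_profile"))
  res <- strsplit(ref$sequence, "")[[1]]
  bw <- rep("", length(res))
  bw[ref$bw_map$index] <- ref$bw_map$bw
  tab <- data.frame(index = seq_along(res), residue = res, bw = bw)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_profile
#' @export
read_reference_profile <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           colClasses = c("integer", "character", "character"),
                           na.strings = NULL)
  sequence <- paste(tab$residue, collapse = "")
  keep <- nzchar(tab$bw)
  build_reference(sequence, data.frame(index = tab$index[keep],
                                       bw = tab$bw[keep]))
}

# helix architecture shared by the synthetic profiles: bw position range of
# each annotated TM span (class-A convention, consecutive numbering)
.helix_arch <- list(
  `1` = c(30L, 59L), `2` = c(38L, 65L), `3` = c(22L, 55L), `4` = c(39L, 62L),
  `5` = c(35L, 67L), `6` = c(30L, 61L), `7` = c(32L, 55L)
)

# hand-built TM helix sequences with landmarks at the class-A offsets; the
# binding-pocket positions mirror an aminergic template (D3.32; Ser at
# 5.42/5.43/5.46; aromatic cage W6.48/F6.51/F6.52; N6.55)
.helix_seqs <- c(
  # 1.30-1.59; N1.50 at offset 21
  "WVVGMAILCVLIVTSIVLAGNLVMLSVFTQ",
  # 2.38-2.65; D2.50 at offset 13
  "LNLFVLSLAVADDLVALLVMPFSLANEL",
  # 3.22-3.55; D3.32 at offset 11, E/DRY at offsets 28-30
  "WLFGAFLCELDVAMDVMLCTASIFNLCDRYWAIT",
  # 4.39-4.62; W4.50 at offset 12
  "RVAVMIAAVWLWSLLVTFPPLLGW",
  # 5.35-5.67; A5.39 (5), S5.42 (8), S5.43 (9), S5.46 (12), P5.50 (16)
  "NFVIAYTSSVISFYIPLAVMLVMYGRIYVTARR",
  # 6.30-6.61; W6.48 (19), P6.50 (21), N6.55 (26)
  "KAAKTLGIVMGVFILCTLWLPFFLANVINRFY",
  # 7.32-7.55; N7.49 (18), P7.50 (19), Y7.53 (22)
  "EMWIGYLNSGLNPVIYTNPSMYAR"
)

# build a full profile from helix sequences plus loop sequences; loops is a
# character vector of length 8: Nterm, ICL1, ECL1, ICL2, ECL2, ICL3, ECL3,
# Cterm. Used by the shipped synthetic reference and by the simulator.
.assemble_profile <- function(helices = .helix_seqs, loops) {
  stopifnot(length(helices) == 7L, length(loops) == 8L)
  lens <- vapply(.helix_arch, function(x) x[2] - x[1] + 1L, integer(1))
  if (!all(nchar(helices) == lens)) {
    stop("helix sequence lengths do not match the helix architecture")
  }
  seq <- loops[1]
  rows <- list()
  for (h in 1:7) {
    start_idx <- nchar(seq) + 1L
    seq <- paste0(seq, helices[h])
    posr <- .helix_arch[[h]]
    rows[[h]] <- data.frame(
      index = seq.int(start_idx, start_idx + lens[h] - 1L),
      bw = sprintf("%d.%02d", h, seq.int(posr[1], posr[2]))
    )
    seq <- paste0(seq, loops[h + 1])
  }
  list(sequence = seq, bw_map = do.call(rbind, rows))
}

# deterministic pseudo-random loop of a given length (loops are
# low-constraint in class-A receptors; any composition works for alignment)
.loop_seq <- function(n, phase = 0L) {
  pool <- strsplit("GSTAPQNEDKRH", "")[[1]]
  if (n == 0L) return("")
  paste(pool[((seq_len(n) * 5L + phase) %% length(pool)) + 1L], collapse = "")
}

#' Synthetic class-A reference profile
#'
#' Constructs the package's built-in annotated template: a synthetic class-A
#' GPCR with seven transmembrane helices carrying the canonical landmarks
#' (N1.50, D2.50, DRY at 3.49-3.51, W4.50, P5.50, P6.50, NPxxY at
#' 7.49-7.53) and an aminergic-style binding pocket (Asp3.32, serines at
#' 5.42/5.43/5.46). It plays the role of the annotated aminergic template a
#' user would normally derive from a solved receptor structure; the same
#' profile is shipped as `inst/extdata/reference_synthetic_class_a.tsv`.
#'
#' @return A `reference_profile`.
#' @seealso [build_reference()], [default_reference()]
#' @export
synthetic_reference_profile <- function() {
  loops <- c(.loop_seq(25, 0L), .loop_seq(6, 1L), .loop_seq(6, 2L),
             .loop_seq(8, 3L), .loop_seq(20, 4L), .loop_seq(18, 5L),
             .loop_seq(5, 6L), .loop_seq(15, 7L))
  parts <- .assemble_profile(loops = loops)
  build_reference(parts$sequence, parts$bw_map)
}

#' The shipped reference profile
#'
#' Reads the synthetic class-A reference profile installed with the package.
#' Identical to [synthetic_reference_profile()]; shipping it as a versioned
#' data file documents the exact numbering template used by a given release.
#'
#' @return A `reference_profile`.
#' @export
default_reference <- function() {
  path <- system.file("extdata", "reference_synthetic_class_a.tsv",
                      package = "amrec", mustWork = TRUE)
  read_reference_profile(path)
}
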