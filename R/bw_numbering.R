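# Generic-number assignment by landmark-verified global alignment.
#
# A query receptor inherits generic numbers through the aligned (non-gap)
# columns of a global alignment to an annotated reference. Numbering is
# never extrapolated across indels inside a TM span: helices containing an
# internal indel, or whose x.50 anchor fails to align, are flagged
# low-confidence so the motif census can refuse to read positions from them.

#' Alignment parameters
#'
#' Defaults: BLOSUM62 substitution scores with affine gap penalties
#' (opening 10, extension 0.5). Alignment is deterministic for fixed
#' parameters (Needleman-Wunsch with a fixed traceback preference).
#'
#' @param substitution_matrix name of a substitution matrix known to
#'   [Biostrings::pairwiseAlignment()].
#' @param gap_opening,gap_extension affine gap penalties (positive costs).
#' @return A list of class `align_params`.
#' @export
align_params <- function(substitution_matrix = "BLOSUM62",
                         gap_opening = 10, gap_extension = 0.5) {
  stopifnot(gap_opening >= 0, gap_extension >= 0)
  structure(list(substitution_matrix = substitution_matrix,
                 gap_opening = gap_opening, gap_extension = gap_extension),
            class = "align_params")
}

.align_strings <- function(a, b, params) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(a), subject = Biostrings::AAString(b),
    type = "global", substitutionMatrix = params$substitution_matrix,
    gapOpening = params$gap_opening, gapExtension = params$gap_extension
  )
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

#' Globally align a query receptor to a reference profile
#'
#' @param query amino-acid string (full-length receptor, >= 100 residues).
#' @param ref a [build_reference()] profile.
#' @param params an [align_params()] list.
#' @return An object of class `pairwise_alignment` with equal-length aligned
#'   strings `query_aligned` and `ref_aligned` (gap character `-`), the
#'   alignment `score` and the `params` used.
#' @export
align_to_reference <- function(query, ref, params = align_params()) {
  query <- toupper(query)
  stopifnot(inherits(ref, "reference_profile"))
  if (nchar(query) < 100L) {
    stop("query shorter than 100 residues: not a full-length receptor",
         call. = FALSE)
  }
  .check_aa(query, "query")
  al <- .align_strings(query, ref$sequence, params)
  structure(list(query_aligned = al$a, ref_aligned = al$b,
                 score = al$score, params = params),
            class = "pairwise_alignment")
}

#' Assign Ballesteros-Weinstein numbers to a query receptor
#'
#' Each query residue aligned to an annotated reference residue inherits its
#' generic number; residues aligned to gaps or to unannotated loop positions
#' receive none. The landmark report records, for every configured landmark,
#' whether the query carries the expected residue (`found`), a different
#' residue (`mismatch`) or no residue (`gapped`). A helix is flagged
#' low-confidence when its x.50 anchor is not `found` or when the alignment
#' places an indel inside its annotated TM span.
#'
#' @param query amino-acid string, or a single-row subset of a
#'   `receptor_set`.
#' @param ref a `reference_profile`.
#' @param params an [align_params()] list.
#' @param id identifier stored in the annotation.
#' @return An object of class `bw_annotation`: fields `id`, `map` (data
#'   frame `index`, `residue`, `bw`), `lookup` (named index vector keyed by
#'   generic number), `landmarks` (report), `low_conf_helices`,
#'   `indel_helices` and `alignment`.
#' @export
assign_bw <- function(query, ref, params = align_params(), id = "query") {
  if (inherits(query, "receptor_set")) {
    stopifnot(nrow(query) == 1L)
    id <- query$id[1]
    query <- query$sequence[1]
  }
  query <- toupper(query)
  aln <- align_to_reference(query, ref, params)
  qa <- strsplit(aln$query_aligned, "")[[1]]
  ra <- strsplit(aln$ref_aligned, "")[[1]]
  qi <- cumsum(qa != "-")
  ri <- cumsum(ra != "-")
  both <- qa != "-" & ra != "-"
  ref_bw <- character(nchar(ref$sequence))
  ref_bw[ref$bw_map$index] <- ref$bw_map$bw
  # inherit numbers through aligned columns on annotated reference residues
  qidx <- qi[both]
  bw <- ref_bw[ri[both]]
  keep <- nzchar(bw)
  map <- data.frame(index = qidx[keep],
                    residue = qa[both][keep],
                    bw = bw[keep], stringsAsFactors = FALSE)
  lookup <- stats::setNames(map$index, map$bw)

  # landmark report
  lm <- ref$landmarks
  report <- data.frame(name = lm$name, bw = lm$bw, expected = lm$expected,
                       status = "gapped", index = NA_integer_,
                       residue = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(lm))) {
    hit <- match(lm$bw[k], map$bw)
    if (!is.na(hit)) {
      obs <- map$residue[hit]
      okset <- strsplit(lm$expected[k], "|", fixed = TRUE)[[1]]
      report$status[k] <- if (obs %in% okset) "found" else "mismatch"
      report$index[k] <- map$index[hit]
      report$residue[k] <- obs
    }
  }
  anchors_bad <- report$bw %in% .bw_anchors & report$status != "found"
  if (sum(anchors_bad) >= 2L) {
    stop(sprintf("not a numberable GPCR: %d x.50 anchors unmatched (%s)",
                 sum(anchors_bad),
                 paste(report$bw[anchors_bad], collapse = ", ")),
         call. = FALSE)
  }

  # indel-in-helix: any alignment column with a gap whose reference context
  # lies strictly within an annotated TM span
  indel_helices <- integer(0)
  for (h in ref$helix_spans$helix) {
    span <- ref$helix_spans[ref$helix_spans$helix == h, ]
    # deletion: query gap aligned to a reference residue inside the span
    del <- qa == "-" & ra != "-" & ri >= span$first & ri <= span$last
    # insertion: extra query residue between two reference residues of the span
    ins <- ra == "-" & ri >= span$first & ri < span$last
    if (any(del) || any(ins)) indel_helices <- c(indel_helices, h)
  }
  anchor_helix <- .bw_helix(report$bw[report$bw %in% .bw_anchors &
                                        report$status != "found"])
  low_conf <- sort(unique(c(indel_helices, anchor_helix)))

  structure(list(id = id, map = map, lookup = lookup, landmarks = report,
                 low_conf_helices = low_conf, indel_helices = indel_helices,
                 alignment = aln),
            class = "bw_annotation")
}

#' @export
print.bw_annotation <- function(x, ...) {
  cat(sprintf("BW annotation for '%s': %d numbered residues\n",
              x$id, nrow(x$map)))
  bad <- x$landmarks[x$landmarks$status != "found", , drop = FALSE]
  if (nrow(bad)) {
    cat("  landmark issues:",
        paste(sprintf("%s=%s", bad$bw, bad$status), collapse = ", "), "\n")
  } else {
    cat("  all landmarks found\n")
  }
  if (length(x$low_conf_helices)) {
    cat("  low-confidence helices:",
        paste(x$low_conf_helices, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Look up the residue at a generic number
#'
#' @param annotation a `bw_annotation`.
#' @param generic_number string `"h.pp"`, e.g. `"3.32"`.
#' @return A list with `index` (1-based residue index), `residue` (letter)
#'   and `status` (`"assigned"` or `"absent"`); `index`/`residue` are `NA`
#'   when the position was gapped or unannotated.
#' @export
residue_at <- function(annotation, generic_number) {
  stopifnot(inherits(annotation, "bw_annotation"))
  if (!grepl("^[1-7]\\.[0-9]{2}$", generic_number)) {
    stop("malformed generic number: '", generic_number,
         "' (expected \"h.pp\")", call. = FALSE)
  }
  hit <- match(generic_number, annotation$map$bw)
  if (is.na(hit)) {
    return(list(index = NA_integer_, residue = NA_character_,
                status = "absent"))
  }
  list(index = annotation$map$index[hit],
       residue = annotation$map$residue[hit], status = "assigned")
}

#' Percent identity between two sequences
#'
#' Computed over a global alignment; identity = identical columns divided by
#' all alignment columns excluding dual-gap columns (which cannot occur in a
#' pairwise global alignment), times 100. The denominator convention is
#' recorded in the `denominator` attribute of the result.
#'
#' @param a,b amino-acid strings.
#' @param params an [align_params()] list.
#' @return Percent identity (numeric scalar in \[0, 100\]).
#' @export
pairwise_identity <- function(a, b, params = align_params()) {
  a <- toupper(a); b <- toupper(b)
  stopifnot(nzchar(a), nzchar(b))
  al <- .align_strings(a, b, params)
  x <- strsplit(al$a, "")[[1]]
  y <- strsplit(al$b, "")[[1]]
  cmp <- !(x == "-" & y == "-")
  ident <- 100 * sum(x == y & x != "-") / sum(cmp)
  attr(ident, "denominator") <- "aligned columns excluding dual-gap columns"
  ident
}

#' Annotate every receptor in a set
#'
#' Runs [assign_bw()] on each receptor, converting annotation failures
#' (e.g. unnumberable sequences) into exclusion records instead of errors,
#' so a census over the set can report them.
#'
#' @param x a `receptor_set`.
#' @param ref a `reference_profile`.
#' @param params an [align_params()] list.
#' @return A list with `annotations` (named list of `bw_annotation`) and
#'   `excluded` (data frame `id`, `reason`).
#' @export
annotate_set <- function(x, ref, params = align_params()) {
  stopifnot(inherits(x, "receptor_set"))
  anns <- list()
  excluded <- data.frame(id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(x))) {
    res <- tryCatch(assign_bw(x$sequence[i], ref, params, id = x$id[i]),
                    error = function(e) conditionMessage(e))
    if (inherits(res, "bw_annotation")) {
      anns[[x$id[i]]] <- res
    } else {
      excluded <- rbind(excluded, data.frame(id = x$id[i], reason = res,
                                             stringsAsFactors = FALSE))
    }
  }
  list(annotations = anns, excluded = excluded)
}
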