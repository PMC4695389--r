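# Pooled-mixture screening: design, hit calling, deconvolution.
#
# De-orphanization screens test chemicals in pools; a receptor hit on a
# pool nominates every pool member as a candidate agonist, and single-
# compound follow-up partitions candidates into confirmed and rejected.

#' Construct a mixture design
#'
#' @param table data frame with columns `mix_id`, `chemical` and optional
#'   `concentration_uM` (micromolar concentration of each chemical in its
#'   mix; stored internally in molar).
#' @return An object of class `mixture_design`: named list `mixes`
#'   (mix id -> chemical vector) plus `concentration` (molar, per
#'   chemical).
#' @export
mixture_design <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("mix_id", "chemical") %in% names(table)))
  conc_uM <- if ("concentration_uM" %in% names(table))
    table$concentration_uM else rep(83.3, nrow(table))
  if (any(conc_uM <= 0)) stop("concentrations must be positive",
                              call. = FALSE)
  mixes <- split(table$chemical, table$mix_id)
  for (m in names(mixes)) {
    if (length(mixes[[m]]) == 0L) stop("empty mix: ", m, call. = FALSE)
    if (anyDuplicated(mixes[[m]])) {
      stop("duplicate chemical within mix ", m, call. = FALSE)
    }
  }
  conc <- split(conc_uM * 1e-6, table$mix_id)
  structure(list(mixes = mixes, concentration = conc),
            class = "mixture_design")
}

#' The shipped 11-pool screening design
#'
#' Reads the package's transcription of an 11-mix amine screening panel
#' (5-6 chemicals per pool at 83.3 uM each) from `inst/extdata`.
#'
#' @return A `mixture_design`.
#' @export
default_mixture_design <- function() {
  path <- system.file("extdata", "mixture_design.tsv", package = "amrec",
                      mustWork = TRUE)
  mixture_design(utils::read.table(path, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE, quote = ""))
}

#' @export
print.mixture_design <- function(x, ...) {
  cat(sprintf("Mixture design: %d pools, %d chemicals\n",
              length(x$mixes), length(unique(unlist(x$mixes)))))
  for (m in names(x$mixes)) {
    cat(sprintf("  %s (%d): %s\n", m, length(x$mixes[[m]]),
                paste(x$mixes[[m]], collapse = ", ")))
  }
  invisible(x)
}

#' Call screen hits from pooled responses
#'
#' Computes, per (receptor, mix), the fold change of the mean response over
#' the mean no-receptor control response and flags pools at or above the
#' threshold. The screen threshold is a configuration choice, not a fixed
#' constant.
#'
#' @param tab data frame with columns `receptor`, `mix_id`, `response`,
#'   `is_control` (logical; control rows are no-receptor wells and may have
#'   `NA` receptor).
#' @param threshold fold-over-control cutoff for a hit (default 2).
#' @return An object of class `screen_result`: data frame `receptor`,
#'   `mix_id`, `fold`, `hit` with attribute `threshold`.
#' @export
call_screen_hits <- function(tab, threshold = 2) {
  stopifnot(all(c("receptor", "mix_id", "response", "is_control") %in%
                  names(tab)))
  ctrl <- mean(tab$response[tab$is_control])
  if (!is.finite(ctrl) || ctrl <= 0) {
    stop("control responses missing or non-positive", call. = FALSE)
  }
  d <- tab[!tab$is_control, , drop = FALSE]
  agg <- stats::aggregate(response ~ receptor + mix_id, data = d, FUN = mean)
  agg$fold <- agg$response / ctrl
  agg$hit <- agg$fold >= threshold
  out <- agg[order(agg$receptor, agg$mix_id),
             c("receptor", "mix_id", "fold", "hit")]
  rownames(out) <- NULL
  structure(out, class = c("screen_result", "data.frame"),
            threshold = threshold)
}

#' Deconvolve mixture hits into candidate chemicals
#'
#' Candidates are the union of all chemicals in the hit pools. When
#' single-compound follow-up results are provided, candidates are
#' partitioned into confirmed, rejected and untested; the candidate set
#' itself never shrinks when another hit pool is added.
#'
#' @param design a [mixture_design()].
#' @param hits character vector of hit mix ids.
#' @param followup optional named logical vector, chemical -> active in
#'   single-compound follow-up.
#' @return A list with `candidates` (character vector) and, when follow-up
#'   is given, `confirmed`, `rejected`, `untested`.
#' @export
deconvolve_mixture_hits <- function(design, hits, followup = NULL) {
  stopifnot(inherits(design, "mixture_design"))
  unknown <- setdiff(hits, names(design$mixes))
  if (length(unknown)) {
    stop("hit mix id(s) not in design: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  candidates <- unique(unlist(design$mixes[hits], use.names = FALSE))
  if (is.null(candidates)) candidates <- character(0)
  out <- list(candidates = candidates)
  if (!is.null(followup)) {
    tested <- intersect(candidates, names(followup))
    out$confirmed <- tested[followup[tested]]
    out$rejected <- tested[!followup[tested]]
    out$untested <- setdiff(candidates, tested)
  }
  out
}
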