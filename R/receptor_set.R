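#' @keywords internal
#' @importFrom stats coef predict residuals simulate
#' @importFrom graphics plot
"_PACKAGE"

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Construct a receptor set
#'
#' A receptor set holds one row per receptor: a protein sequence plus the
#' metadata used for grouping (species, family/group, clade). It is the
#' package's container for receptor repertoires such as the 112-member
#' zebrafish TAAR family or the mouse biogenic amine receptors.
#'
#' @param id character vector of unique receptor identifiers.
#' @param sequence character vector of amino-acid sequences (20-letter
#'   alphabet plus the ambiguity letter `X`); lowercase input is uppercased.
#' @param species,group,clade,accession optional per-receptor metadata.
#' @param provenance free-text note recording where the set came from.
#' @return An object of class `receptor_set`: a data frame with columns
#'   `id`, `species`, `group`, `clade`, `accession`, `sequence` and a
#'   `provenance` attribute. Input order is preserved.
#' @examples
#' rs <- receptor_set(id = c("r1", "r2"), sequence = c("MDILA", "MEILA"))
#' nrow(rs)
#' @export
receptor_set <- function(id, sequence, species = NA_character_,
                         group = NA_character_, clade = NA_character_,
                         accession = NA_character_,
                         provenance = "constructed in R") {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence)) {
    stop("'id' and 'sequence' must have the same length", call. = FALSE)
  }
  dup <- id[duplicated(id)]
  if (length(dup)) {
    stop("duplicate receptor id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(sequence))) {
    stop("empty sequence for id(s): ",
         paste(id[!nzchar(sequence)], collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(sequence)) {
    .check_aa(sequence[i], id[i])
  }
  out <- data.frame(
    id = id,
    species = rep_len(as.character(species), length(id)),
    group = rep_len(as.character(group), length(id)),
    clade = rep_len(as.character(clade), length(id)),
    accession = rep_len(as.character(accession), length(id)),
    sequence = sequence,
    stringsAsFactors = FALSE
  )
  attr(out, "provenance") <- provenance
  class(out) <- c("receptor_set", "data.frame")
  out
}

# validate one amino-acid string; errors name the offending position
.check_aa <- function(seq, id) {
  letters_vec <- strsplit(seq, "")[[1]]
  bad <- which(!(letters_vec %in% AA_ALPHABET))
  if (length(bad)) {
    stop(sprintf("invalid amino-acid letter '%s' at position %d in '%s'",
                 letters_vec[bad[1]], bad[1], id), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.receptor_set <- function(x, ...) {
  cat(sprintf("Receptor set: %d sequence(s)\n", nrow(x)))
  cat(sprintf("  provenance: %s\n", attr(x, "provenance") %||% "unknown"))
  grp <- table(x$group, useNA = "ifany")
  if (length(grp) > 1L || !all(is.na(x$group))) {
    cat("  groups:", paste(sprintf("%s (%d)", names(grp), grp), collapse = ", "),
        "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a FASTA file into a receptor set
#'
#' Headers are split at the first whitespace; the leading token becomes the
#' receptor id. Sequences are uppercased and validated against the amino-acid
#' alphabet (plus `X`). Metadata columns are filled with `NA` and can be
#' merged later with [merge_metadata()].
#'
#' @param path path to a FASTA file of protein sequences.
#' @return A [receptor_set()] with one record per FASTA entry, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  aas <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(aas) == 0L) {
    stop("malformed FASTA: no sequence entries in ", path, call. = FALSE)
  }
  ids <- vapply(strsplit(names(aas), "[ \t]+"), `[[`, character(1), 1L)
  receptor_set(id = ids, sequence = as.character(aas),
               provenance = paste0("read_fasta(", path, ")"))
}

#' Write a receptor set to FASTA
#'
#' @param x a `receptor_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "receptor_set"))
  lines <- character(0)
  for (i in seq_len(nrow(x))) {
    lines <- c(lines, paste0(">", x$id[i]), x$sequence[i])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a receptor metadata table
#'
#' The table must be tab- or comma-delimited with a header containing at
#' least `id`, `species` and `group`; `clade` and `accession` are optional.
#' Extra columns are ignored with a warning. Rows whose id does not occur in
#' a given FASTA are retained here; [merge_metadata()] reports them.
#'
#' @param path path to a delimited metadata table.
#' @return A data frame with columns `id`, `species`, `group`, `clade`,
#'   `accession`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  required <- c("id", "species", "group")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("metadata table missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  known <- c(required, "clade", "accession")
  extra <- setdiff(names(tab), known)
  if (length(extra)) {
    warning("ignoring unknown metadata column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  dup <- tab$id[duplicated(tab$id)]
  if (length(dup)) {
    stop("duplicated metadata row(s) for id(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  for (col in c("clade", "accession")) {
    if (is.null(tab[[col]])) tab[[col]] <- NA_character_
  }
  tab[, known]
}

#' Merge metadata into a receptor set
#'
#' Joins by id; receptors without a metadata row keep `NA` fields, metadata
#' rows without a matching receptor are reported in the `unmatched`
#' attribute of the result.
#'
#' @param x a `receptor_set`.
#' @param metadata a data frame from [read_metadata()].
#' @return `x` with metadata columns filled; attribute `unmatched` holds the
#'   ids of metadata rows absent from `x`.
#' @export
merge_metadata <- function(x, metadata) {
  stopifnot(inherits(x, "receptor_set"))
  idx <- match(x$id, metadata$id)
  for (col in c("species", "group", "clade", "accession")) {
    hit <- !is.na(idx)
    x[[col]][hit] <- metadata[[col]][idx[hit]]
  }
  unmatched <- setdiff(metadata$id, x$id)
  if (length(unmatched)) {
    message("metadata rows with no matching receptor: ",
            paste(unmatched, collapse = ", "))
  }
  attr(x, "unmatched") <- unmatched
  x
}
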