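# Motif census over receptor repertoires.
#
# Biogenic amine receptors contact ligand amino groups through an aspartate
# at generic position 3.32 (helix III); a second, non-canonical contact site
# is an aspartate at 5.42 (helix V), with some mammalian receptors carrying
# the acid one turn later at 5.43. The census classifies every receptor into
# X_only (anion at 3.32 only), Y_only (anion at 5.42/5.43 only), both, or
# neither, and tabulates counts per receptor group.

CENSUS_CATEGORIES <- c("X_only", "Y_only", "both", "neither")

#' Extract the amine-recognition motif profile of one receptor
#'
#' Reads the residues at the configured generic positions from a
#' [assign_bw()] annotation. Positions on a low-confidence helix (failed
#' x.50 anchor or internal TM indel), or occupied by the ambiguity letter
#' `X`, report state `"unknown"`; gapped positions report `"absent"`.
#' States are only ever derived from an annotation, never from raw
#' sequence offsets.
#'
#' @param annotation a `bw_annotation`.
#' @param positions character vector of generic numbers; the census needs
#'   at least 3.32, 5.42 and 5.43.
#' @return An object of class `motif_profile`: `id` plus a named character
#'   vector `states` with values in `D`, `E`, `other:<letter>`, `absent`,
#'   `unknown`.
#' @export
extract_motif_profile <- function(annotation,
                                  positions = c("3.32", "5.42", "5.43")) {
  stopifnot(inherits(annotation, "bw_annotation"))
  states <- character(length(positions))
  names(states) <- positions
  for (p in positions) {
    h <- .bw_helix(p)
    if (h %in% annotation$low_conf_helices) {
      states[p] <- "unknown"
      next
    }
    r <- residue_at(annotation, p)
    states[p] <- if (r$status == "absent") {
      "absent"
    } else if (r$residue == "X") {
      "unknown"
    } else if (r$residue %in% c("D", "E")) {
      r$residue
    } else {
      paste0("other:", r$residue)
    }
  }
  structure(list(id = annotation$id, states = states),
            class = "motif_profile")
}

# does a state qualify as the acidic motif under the given mode?
.qualifies <- function(state, acid_mode) {
  if (acid_mode == "asp_only") state == "D" else state %in% c("D", "E")
}

#' Classify a receptor into a motif category
#'
#' X is true when position 3.32 carries the acid (aspartate, or glutamate
#' too under `acid_mode = "anion_DE"`); Y is true when 5.42 carries it, or
#' 5.43 when the fallback is enabled (some mammalian TAARs position the
#' helix-V acid one turn later). Receptors with an `"unknown"` state at a
#' position that would decide the category raise an error with a reason;
#' [census()] converts these into exclusion records.
#'
#' @param profile a `motif_profile`.
#' @param acid_mode `"asp_only"` (aspartate only) or `"anion_DE"`
#'   (aspartate or glutamate).
#' @param y_positions `"5.42"` or `"5.42_or_5.43"` (enables the 5.43
#'   fallback).
#' @return An object of class `receptor_category`: `category` in
#'   `X_only`/`Y_only`/`both`/`neither`, with basis flags `x_is_glu` (the
#'   3.32 anion is glutamate) and `y_is_543` (the helix-V anion was found
#'   at 5.43, not 5.42).
#' @export
classify_receptor <- function(profile, acid_mode = c("asp_only", "anion_DE"),
                              y_positions = c("5.42", "5.42_or_5.43")) {
  stopifnot(inherits(profile, "motif_profile"))
  acid_mode <- match.arg(acid_mode)
  y_positions <- match.arg(y_positions)
  st <- profile$states
  need <- c("3.32", "5.42", if (y_positions == "5.42_or_5.43") "5.43")
  if (any(!need %in% names(st))) {
    stop("profile lacks configured position(s): ",
         paste(setdiff(need, names(st)), collapse = ", "), call. = FALSE)
  }
  if (st[["3.32"]] == "unknown") {
    stop("state at 3.32 unknown for '", profile$id, "'", call. = FALSE)
  }
  x <- .qualifies(st[["3.32"]], acid_mode)
  y42 <- st[["5.42"]]
  y43 <- if (y_positions == "5.42_or_5.43") st[["5.43"]] else NULL
  q42 <- if (y42 == "unknown") NA else .qualifies(y42, acid_mode)
  q43 <- if (is.null(y43)) FALSE else if (y43 == "unknown") NA else
    .qualifies(y43, acid_mode)
  # three-valued OR: TRUE dominates unknown, unknown dominates FALSE
  y <- if (isTRUE(q42) || isTRUE(q43)) TRUE else
    if (is.na(q42) || is.na(q43)) NA else FALSE
  if (is.na(y)) {
    stop("state at helix-V position unknown for '", profile$id, "'",
         call. = FALSE)
  }
  category <- if (x && y) "both" else if (x) "X_only" else
    if (y) "Y_only" else "neither"
  structure(list(
    category = category,
    x_is_glu = x && st[["3.32"]] == "E",
    y_is_543 = isTRUE(q43) && !isTRUE(q42)
  ), class = "receptor_category")
}

#' Tabulate motif categories per receptor group
#'
#' The machine twin of a per-family anion census: one row per receptor
#' group with counts of the four motif categories. Receptors without a
#' usable annotation, or with an unknown state at a deciding position, are
#' excluded with a reason and listed in the `excluded` attribute; all
#' others appear in exactly one category, so the four counts always sum to
#' the row total.
#'
#' @param x a `receptor_set` (grouping comes from its metadata columns).
#' @param annotations result of [annotate_set()], or a named list of
#'   `bw_annotation` objects.
#' @param group_by metadata column used as the grouping key (`"group"`,
#'   `"species"` or `"clade"`).
#' @param acid_mode,y_positions see [classify_receptor()].
#' @return An object of class `census_table`: a data frame with columns
#'   `group`, `X_only`, `Y_only`, `both`, `neither`, `total`, plus
#'   attributes `assignments` (per-receptor table), `excluded`,
#'   `acid_mode`, `y_positions`.
#' @export
census <- function(x, annotations, group_by = "group",
                   acid_mode = c("asp_only", "anion_DE"),
                   y_positions = c("5.42", "5.42_or_5.43")) {
  stopifnot(inherits(x, "receptor_set"),
            group_by %in% c("group", "species", "clade"))
  acid_mode <- match.arg(acid_mode)
  y_positions <- match.arg(y_positions)
  excluded <- data.frame(id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  if (is.list(annotations) && !is.null(annotations$annotations)) {
    excluded <- rbind(excluded, annotations$excluded)
    annotations <- annotations$annotations
  }
  grp_all <- x[[group_by]]
  grp_all[is.na(grp_all)] <- "(ungrouped)"
  rows <- list()
  for (i in seq_len(nrow(x))) {
    rid <- x$id[i]
    grp <- grp_all[i]
    ann <- annotations[[rid]]
    if (is.null(ann)) {
      if (!rid %in% excluded$id) {
        excluded <- rbind(excluded, data.frame(id = rid,
                                               reason = "no annotation"))
      }
      next
    }
    prof <- extract_motif_profile(ann)
    cls <- tryCatch(classify_receptor(prof, acid_mode, y_positions),
                    error = function(e) conditionMessage(e))
    if (!inherits(cls, "receptor_category")) {
      excluded <- rbind(excluded, data.frame(id = rid, reason = cls))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      id = rid, group = grp,
      state_3.32 = prof$states[["3.32"]],
      state_5.42 = prof$states[["5.42"]],
      state_5.43 = if ("5.43" %in% names(prof$states))
        prof$states[["5.43"]] else NA_character_,
      category = cls$category, x_is_glu = cls$x_is_glu,
      y_is_543 = cls$y_is_543, stringsAsFactors = FALSE
    )
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), group = character(0),
               state_3.32 = character(0), state_5.42 = character(0),
               state_5.43 = character(0), category = character(0),
               x_is_glu = logical(0), y_is_543 = logical(0))
  groups <- unique(grp_all)
  tab <- do.call(rbind, lapply(groups, function(g) {
    sub <- assignments[assignments$group %in% g, , drop = FALSE]
    counts <- vapply(CENSUS_CATEGORIES,
                     function(k) sum(sub$category == k), integer(1))
    if (nrow(sub) == 0L) {
      warning("group '", g, "' has no categorized receptors", call. = FALSE)
    }
    data.frame(group = g, t(counts), total = nrow(sub),
               stringsAsFactors = FALSE)
  }))
  if (is.null(tab)) {
    tab <- data.frame(group = character(0), X_only = integer(0),
                      Y_only = integer(0), both = integer(0),
                      neither = integer(0), total = integer(0))
  }
  rownames(tab) <- NULL
  structure(tab, class = c("census_table", "data.frame"),
            assignments = assignments, excluded = excluded,
            acid_mode = acid_mode, y_positions = y_positions)
}

#' @export
print.census_table <- function(x, ...) {
  cat(sprintf("Motif census (acid mode: %s, Y positions: %s)\n",
              attr(x, "acid_mode"), attr(x, "y_positions")))
  print.data.frame(x, row.names = FALSE)
  exc <- attr(x, "excluded")
  if (NROW(exc)) cat(sprintf("%d receptor(s) excluded with reasons\n",
                             nrow(exc)))
  invisible(x)
}

#' Per-character presence/absence matrix for ancestral reconstruction
#'
#' Converts census assignments into the two binary characters used by the
#' phylogenetic layer: X (anion present at 3.32) and Y (anion present at
#' 5.42, or 5.43 under the fallback). Excluded receptors get `?`.
#'
#' @param census_table a [census()] result.
#' @param ids optional tip ids to include, in order (defaults to all
#'   categorized plus excluded receptors).
#' @return A data frame with columns `id`, `X`, `Y` (values `"0"`, `"1"`,
#'   `"?"`), class `character_matrix`.
#' @export
character_matrix <- function(census_table, ids = NULL) {
  stopifnot(inherits(census_table, "census_table"))
  asg <- attr(census_table, "assignments")
  exc <- attr(census_table, "excluded")
  if (is.null(ids)) ids <- c(asg$id, exc$id)
  hit <- match(ids, asg$id)
  X <- Y <- rep("?", length(ids))
  cat_of <- asg$category[hit]
  known <- !is.na(hit)
  X[known] <- ifelse(cat_of[known] %in% c("X_only", "both"), "1", "0")
  Y[known] <- ifelse(cat_of[known] %in% c("Y_only", "both"), "1", "0")
  structure(data.frame(id = ids, X = X, Y = Y, stringsAsFactors = FALSE),
            class = c("character_matrix", "data.frame"))
}
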