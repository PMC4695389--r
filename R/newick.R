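#' Read a Newick tree
#'
#' Thin wrapper around [ape::read.tree()] that validates the tree for use in
#' the motif-evolution pipeline: unique tip labels and non-negative branch
#' lengths. Internal node labels (e.g. bootstrap support written by external
#' ML programs) are kept as support strings, never treated as taxa.
#'
#' @param path path to a file containing a single Newick string.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) {
    stop("malformed Newick: unbalanced parentheses in ", path, call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL)
  if (is.null(tree)) stop("malformed Newick in ", path, call. = FALSE)
  validate_tree(tree)
  tree
}

#' Write a tree as Newick
#'
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @param digits decimal digits for branch lengths (default 10); round trips
#'   through [read_newick()] preserve topology, labels and lengths to this
#'   precision.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 10) {
  validate_tree(tree)
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Validate a phylogenetic tree for pipeline use
#'
#' @param tree an [ape::phylo] object.
#' @return `tree`, invisibly; errors on duplicate tips or negative lengths.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree", call. = FALSE)
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup)) {
    stop("duplicate tip label(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch length(s) in tree", call. = FALSE)
  }
  invisible(tree)
}
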