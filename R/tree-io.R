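#' Read a phylogeny from a Newick file or string
#'
#' Parses a Newick tree (e.g. from Phylomatic) into an [ape::phylo]
#' object and normalises it for comparative analysis: polytomies are
#' resolved to binary nodes with zero-length branches (input child order
#' is kept, so the result is deterministic), and missing branch lengths
#' are assigned.  Phylomatic trees frequently lack branch lengths; the
#' default assigns unit lengths to every branch and emits a message, and
#' `branch_lengths = "grafen"` instead applies Grafen's node-depth
#' scaling via [ape::compute.brlen()].
#'
#' @param source Path to a Newick file, or a Newick string (must contain
#'   `"("` and end in `";"` to be treated as text).
#' @param branch_lengths How to treat trees without branch lengths:
#'   `"unit"` (all branches 1, the default), or `"grafen"`.  Trees that
#'   carry branch lengths keep them.
#' @return A rooted binary tree of class `"phylo"` with branch lengths,
#'   unique non-empty tip labels.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
read_newick <- function(source, branch_lengths = c("unit", "grafen")) {
  branch_lengths <- match.arg(branch_lengths)
  stopifnot(is.character(source), length(source) == 1L)
  is_text <- grepl("\\(", source) && grepl(";", source)
  if (!is_text && !file.exists(source)) {
    stop("file not found and not a Newick string: ", source)
  }
  tree <- tryCatch(
    if (is_text) ape::read.tree(text = source) else ape::read.tree(source),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: no tree found")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  validate_tree_labels(tree)
  if (is.null(tree$edge.length)) {
    if (branch_lengths == "unit") {
      tree$edge.length <- rep(1, nrow(tree$edge))
      message("tree has no branch lengths; set all branch lengths to 1.0")
    } else {
      tree <- ape::compute.brlen(tree, method = "Grafen")
      message("tree has no branch lengths; applied Grafen node-depth scaling")
    }
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    tree <- ape::multi2di(tree, random = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  tree
}

validate_tree_labels <- function(tree) {
  tl <- tree$tip.label
  if (any(!nzchar(tl))) stop("empty tip label in tree")
  if (anyDuplicated(tl)) {
    stop("duplicate tip label(s): ",
         paste(unique(tl[duplicated(tl)]), collapse = ", "))
  }
  invisible(tree)
}

#' Write a phylogeny to Newick
#'
#' Thin wrapper around [ape::write.tree()] that keeps enough digits for
#' branch lengths to round-trip to 1e-9.
#'
#' @param tree A `"phylo"` object.
#' @param path Output file; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
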