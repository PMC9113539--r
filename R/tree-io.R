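#' Read a rooted phylogeny from a Newick file
#'
#' Wraps [ape::read.tree()] with the checks the pipeline relies on: unique
#' tip labels, finite non-negative branch lengths (missing lengths become 0
#' with a warning), and a root. Unrooted input is midpoint-rooted — UniFrac
#' and root-to-tip distances need a root, and for trees inferred without an
#' outgroup the midpoint is the conventional stand-in. Midpoint-rooted trees
#' carry `attr(tree, "midpoint_rooted") = TRUE` so the provenance is visible
#' downstream.
#'
#' @param path path to a Newick file, or a Newick string via `text`.
#' @param text optional Newick string (alternative to `path`).
#' @return An [ape::phylo] tree, rooted, with branch lengths.
#' @export
read_tree <- function(path = NULL, text = NULL) {
  tree <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick input")
  dup_check(tree$tip.label, "tip")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(!is.finite(tree$edge.length) | tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  if (!ape::is.rooted(tree)) {
    tree <- phangorn::midpoint(tree)
    attr(tree, "midpoint_rooted") <- TRUE
  }
  tree
}

#' Patristic (tip-to-tip path length) distance matrix
#'
#' Sum of branch lengths along the unique path between every pair of tips,
#' as a labeled `dist` in `tree$tip.label` order.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @return A `dist` over tips with `attr(, "metric") = "patristic"`.
#' @export
patristic_matrix <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  m <- m[tree$tip.label, tree$tip.label]
  as_dist_checked(m, metric = "patristic")
}
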