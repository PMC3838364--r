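#' UPGMA dendrogram from a distance matrix
#'
#' Agglomerative clustering with size-weighted arithmetic-average linkage
#' (true UPGMA). Node heights equal half the average inter-cluster
#' dissimilarity at each merge, so the cophenetic distances of the returned
#' tree reproduce the merge-level dissimilarities and the tree is
#' ultrametric. Labels are sorted before clustering so the result is a
#' deterministic function of the labelled matrix, independent of row order.
#'
#' @param d symmetric labelled dissimilarity matrix (at least 2 labels).
#' @return rooted ultrametric tree of class `phylo` (ape).
#' @examples
#' d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- upgma(d)
#' cophenetic_matrix(tr)  # reproduces d
#' @export
upgma <- function(d) {
  validate_distance_matrix(d)
  if (nrow(d) < 2L) stop("UPGMA needs at least 2 labels")
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  h <- stats::hclust(stats::as.dist(d), method = "average")
  tr <- ape::as.phylo(h)
  tr
}

#' Parse a Newick string or file into a rooted tree
#'
#' @param text Newick string (or a file path when `file = TRUE`).
#' @param file logical; treat `text` as a file path.
#' @return tree of class `phylo`.
#' @export
read_newick <- function(text, file = FALSE) {
  s <- if (file) paste(readLines(text), collapse = "") else text
  n_open <- lengths(regmatches(s, gregexpr("(", s, fixed = TRUE)))
  n_close <- lengths(regmatches(s, gregexpr(")", s, fixed = TRUE)))
  if (n_open != n_close) {
    stop("unbalanced parentheses in Newick input (", n_open, " '(' vs ",
         n_close, " ')')")
  }
  tr <- tryCatch(ape::read.tree(text = s),
                 error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error: no tree found")
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup)) stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    stop("negative branch length(s) in Newick input")
  }
  tr
}

#' Serialize a tree to a Newick string
#'
#' Round trips through [read_newick()] preserve topology, labels and branch
#' lengths to 12 significant digits.
#'
#' @param tree a `phylo` tree.
#' @param path optional file path; when given the string is also written there.
#' @return Newick string (invisibly when `path` is given).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree, digits = 12)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Cophenetic (patristic) distance matrix of a tree
#'
#' `d(i, j)` is the sum of branch lengths on the path between tips `i` and
#' `j`. For a UPGMA dendrogram this recovers twice the merge heights.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @return symmetric labelled matrix of tip-to-tip path lengths.
#' @export
cophenetic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  d <- as.matrix(stats::cophenetic(tree))
  ord <- order(rownames(d))
  d[ord, ord, drop = FALSE]
}

#' Check ultrametricity of a rooted tree
#' @param tree a `phylo` tree.
#' @param tol absolute tolerance on root-to-tip path differences.
#' @return logical.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-9) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  diff(range(depths)) <= tol
}
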