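#' Read and validate a rooted phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] adding the validation the
#' downstream analyses rely on: a single tree, unique tip labels, and
#' nonnegative branch lengths on every edge.
#'
#' @param path Path to a Newick file containing one rooted tree.
#' @return An object of class `phylo`.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("Newick parse error: no tree could be read",
                        call. = FALSE)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L)
      stop("expected a single tree, found ", length(tr), call. = FALSE)
    tr <- tr[[1L]]
  }
  validate_phylogeny(tr)
}

#' @rdname read_newick
#' @param tree A `phylo` object to validate.
#' @export
validate_phylogeny <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate tip label(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and >= 0", call. = FALSE)
  tree
}

#' Phylogenetic variance-covariance matrix
#'
#' Computes the Brownian-motion covariance structure `C` of a tree:
#' `C[i, j]` is the shared root-to-tip path length of tips `i` and `j`,
#' and `C[i, i]` the depth of tip `i`. Rows follow the tree's declared
#' tip order.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return A symmetric positive semidefinite numeric matrix with tip
#'   labels as dimnames.
#' @export
phylo_vcv <- function(tree) {
  validate_phylogeny(tree)
  C <- ape::vcv.phylo(tree)
  if (any(diag(C) <= 0))
    warning("zero-depth tip(s): ",
            paste(rownames(C)[diag(C) <= 0], collapse = ", "))
  C[tree$tip.label, tree$tip.label]
}

#' Total branch length of a tree
#' @param tree A `phylo` object.
#' @return Sum of all branch lengths.
#' @keywords internal
total_branch_length <- function(tree) sum(tree$edge.length)
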