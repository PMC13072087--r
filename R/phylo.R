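#' Parse a Newick string into a validated phylogeny
#'
#' Reads a rooted phylogeny with branch lengths from a Newick string and
#' validates it for comparative analysis: at least two uniquely labelled
#' tips, branch lengths present and non-negative on every edge, and a
#' finite positive root-to-tip distance for every tip. Trees need not be
#' ultrametric and polytomies are accepted as-is.
#'
#' @param text A single Newick string (terminated by `;`).
#' @return An object of class `phylo` (see [ape::read.tree()]).
#' @details Zero-length terminal branches are permitted but trigger a
#'   warning, since two identical tip rows make the phylogenetic
#'   covariance matrix singular; singularity is caught at fit time.
#' @seealso [write_newick()], [prune_tree()], [phylo_vcv()]
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    bad <- if (n_open > n_close) "(" else ")"
    pos <- utils::tail(gregexpr(bad, text, fixed = TRUE)[[1L]], 1L)
    stop("malformed Newick: unbalanced parenthesis at character ", pos)
  }
  if (!grepl(";\\s*$", text)) {
    stop("malformed Newick: missing terminating ';' at character ", nchar(text))
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed Newick near character 1: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("malformed Newick: could not parse tree")
  validate_phylogeny(tree)
}

#' Serialise a phylogeny to a Newick string
#'
#' @param tree A `phylo` object.
#' @return A single Newick string. `parse_newick(write_newick(tree))`
#'   recovers the same topology and branch lengths up to float formatting.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Validate a phylogeny for comparative analysis
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly unchanged, if valid; otherwise an error.
#' @keywords internal
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  n <- length(tree$tip.label)
  if (n < 2L) stop("tree has fewer than 2 tips (", n, ")")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicated tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (any(!nzchar(tree$tip.label))) stop("empty tip label")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length))) {
    bad <- tree$edge[!is.finite(tree$edge.length), 2L]
    lab <- ifelse(bad <= n, tree$tip.label[bad], paste0("internal node ", bad))
    stop("missing branch length on edge(s) leading to: ", paste(lab, collapse = ", "))
  }
  if (any(tree$edge.length < 0)) stop("negative branch length")
  depths <- ape::node.depth.edgelength(tree)[seq_len(n)]
  if (any(!is.finite(depths)) || any(depths <= 0)) {
    stop("non-positive root-to-tip distance for tip(s): ",
         paste(tree$tip.label[depths <= 0], collapse = ", "))
  }
  term <- tree$edge[, 2L] <= n
  if (any(tree$edge.length[term] == 0)) {
    warning("zero-length terminal branch(es): ",
            paste(tree$tip.label[tree$edge[term, 2L][tree$edge.length[term] == 0]],
                  collapse = ", "))
  }
  tree
}

#' Prune a phylogeny to a subset of tips
#'
#' Returns the induced subtree on `keep`: degree-2 internal nodes are
#' suppressed with their branch lengths summed, so root-to-tip distances
#' and pairwise MRCA depths of retained tips are unchanged.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `phylo` object.
#' @export
prune_tree <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing) > 0L) {
    stop("tip label(s) not in tree: ", paste(missing, collapse = ", "))
  }
  if (length(keep) < 2L) stop("need at least 2 tips to keep, got ", length(keep))
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Phylogenetic variance-covariance matrix
#'
#' Builds the matrix V with `V[i, j]` equal to the depth (distance from
#' the root) of the most recent common ancestor of tips i and j, and
#' `V[i, i]` the root-to-tip distance of tip i. Under Brownian motion on
#' the tree, trait values at the tips have covariance proportional to V.
#'
#' @param tree A `phylo` object.
#' @return A symmetric positive semi-definite numeric matrix with tip
#'   labels as dimnames, rows/columns ordered as `tree$tip.label`.
#' @export
phylo_vcv <- function(tree) {
  validate_phylogeny(tree)
  V <- ape::vcv.phylo(tree)
  V[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal (shared-history) entries of V by `lam`,
#' leaving the diagonal unchanged. `lam = 1` returns V (Brownian motion);
#' `lam = 0` returns `diag(V)` (no phylogenetic signal). For
#' `lam` in \[0, 1\] the result is a convex combination of V and diag(V),
#' hence remains positive semi-definite.
#'
#' @param V Symmetric covariance matrix from [phylo_vcv()].
#' @param lam Scalar in \[0, 1\].
#' @return The transformed matrix.
#' @export
lambda_transform <- function(V, lam) {
  stopifnot(is.matrix(V), nrow(V) == ncol(V))
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0 || lam > 1) {
    stop("lambda must be a single value in [0, 1], got ", format(lam))
  }
  d <- diag(V)
  Vl <- lam * V
  diag(Vl) <- d
  Vl
}
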