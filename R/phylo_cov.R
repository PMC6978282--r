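#' Read a rooted phylogeny from Newick text or file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contract the
#' covariance construction needs: a single rooted tree, branch lengths on
#' every edge, unique tip labels.
#'
#' @param text A Newick string, or `NULL` if `file` is given.
#' @param file Path to a Newick file with a single tree.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  tree <- tryCatch(
    if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file),
    warning = function(w) stop("malformed Newick: ", conditionMessage(w)),
    error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick: could not parse a tree")
  if (inherits(tree, "multiPhylo")) stop("expected a single Newick tree")
  validate_phylo(tree)
}

#' Validate a tree for covariance construction
#'
#' @param tree An [ape::phylo] object.
#' @return The tree, invisibly usable downstream.
#' @export
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (ape::Ntip(tree) < 2L) stop("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  tree
}

#' Shared root-path variance-covariance matrix of a tree
#'
#' Entry (i, j) is the summed branch length from the root down to the most
#' recent common ancestor of tips i and j; the diagonal holds root-to-tip
#' depths. Under Brownian motion this is the expected trait covariance among
#' species.
#'
#' @param tree A rooted [ape::phylo] tree with branch lengths.
#' @return An S x S numeric matrix with tip labels as dimnames.
#' @export
shared_path_vcv <- function(tree) {
  validate_phylo(tree)
  ape::vcv(tree)
}

#' Normalise a phylogenetic VCV to a correlation matrix
#'
#' For an ultrametric tree all root-to-tip depths are equal; dividing the VCV
#' by that common depth yields a unit-diagonal correlation matrix, so the
#' model's gamma parameter alone carries the variance scale and lambda keeps
#' its standard interpretation regardless of the tree's time units.
#'
#' @param V Symmetric VCV matrix from [shared_path_vcv()].
#' @param tolerance Maximum allowed relative spread of the diagonal.
#' @return An object of class `phylo_correlation`: the correlation matrix
#'   with a `species_order` attribute giving the tip ordering.
#' @export
to_correlation <- function(V, tolerance = 1e-6) {
  if (!is.matrix(V) || nrow(V) != ncol(V)) stop("V must be square")
  if (max(abs(V - t(V))) > 1e-12 * max(1, max(abs(V)))) stop("V must be symmetric")
  d <- diag(V)
  if (any(d <= 0)) stop("diagonal of V must be positive")
  spread <- (max(d) - min(d)) / max(d)
  if (spread > tolerance) {
    worst <- order(abs(d - stats::median(d)), decreasing = TRUE)[seq_len(min(3L, length(d)))]
    labs <- if (!is.null(rownames(V))) rownames(V)[worst] else as.character(worst)
    stop(sprintf(
      "tree is not ultrametric: root-to-tip depths differ by relative %.3g (worst tips: %s)",
      spread, paste(labs, collapse = ", ")))
  }
  C <- V / mean(d)
  diag(C) <- 1
  structure(C, species_order = rownames(V), class = c("phylo_correlation", "matrix"))
}

#' Phylogenetic correlation matrix straight from a tree
#'
#' Convenience composition of [shared_path_vcv()] and [to_correlation()].
#'
#' @inheritParams shared_path_vcv
#' @inheritParams to_correlation
#' @return A `phylo_correlation` matrix.
#' @export
phylo_correlation <- function(tree, tolerance = 1e-6) {
  to_correlation(shared_path_vcv(tree), tolerance = tolerance)
}

#' Pagel's lambda transform
#'
#' Multiplies every off-diagonal element of a phylogenetic correlation (or
#' covariance) matrix by `lambda`, leaving the diagonal untouched. lambda = 0
#' erases phylogenetic signal (independent species); lambda = 1 returns the
#' Brownian expectation unchanged.
#'
#' @param C Symmetric matrix.
#' @param lambda Scalar in \[0, 1\].
#' @return The transformed matrix (plain matrix, same dimnames).
#' @export
pagel_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  M <- unclass(C) * lambda
  diag(M) <- diag(unclass(C))
  M
}

#' Scale a covariance matrix by gamma
#'
#' Multiplies every element by `gamma > 0`; with a unit-diagonal input,
#' `gamma` is the marginal variance of each species effect.
#'
#' @param M Numeric matrix.
#' @param gamma Positive scalar.
#' @return `gamma * M`.
#' @export
scale_covariance <- function(M, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) || gamma <= 0)
    stop("gamma must be a single value > 0")
  unclass(M) * gamma
}

#' Check (and lightly repair) positive definiteness
#'
#' Attempts a Cholesky factorization; on failure adds a diagonal jitter up to
#' `max_jitter` once and retries. Lambda-transformed correlation matrices of
#' valid trees are positive definite in exact arithmetic, so the jitter only
#' absorbs floating-point loss near lambda = 1 on deep trees.
#'
#' @param M Symmetric matrix.
#' @param max_jitter Largest diagonal jitter to try (default 1e-8).
#' @return `M` (possibly jittered) for which `chol()` succeeds.
#' @export
assert_positive_definite <- function(M, max_jitter = 1e-8) {
  if (max(abs(M - t(M))) > 1e-10 * max(1, max(abs(M))))
    stop("matrix is not symmetric")
  ok <- !inherits(try(chol(M), silent = TRUE), "try-error")
  if (ok) return(M)
  Mj <- M + diag(max_jitter, nrow(M))
  if (inherits(try(chol(Mj), silent = TRUE), "try-error"))
    stop("matrix is not positive definite (Cholesky failed even with jitter)")
  Mj
}

#' Export a labelled matrix to delimited text
#'
#' @param M Matrix with species labels as dimnames.
#' @param path Output path (tab-separated, labels as header row and column).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(M, path) {
  utils::write.table(as.data.frame(unclass(M)), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}
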