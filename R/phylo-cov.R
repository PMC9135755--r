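#' Brownian-motion covariance matrix of a phylogeny
#'
#' Under Brownian trait evolution the expected covariance between two tips is
#' proportional to the length of their shared root-to-MRCA path, and each
#' tip's variance to its root-to-tip distance. Taxa are returned in sorted
#' order so matrices from different calls align.
#'
#' @param tree a rooted `"phylo"` object with branch lengths.
#' @return an n x n symmetric positive-semidefinite matrix with taxon
#'   dimnames, `C[i, i]` the root-to-tip distance of taxon i.
#' @export
bm_covariance <- function(tree) {
  validate_phylogeny(tree)
  C <- ape::vcv.phylo(tree)
  if (max(diag(C)) <= 0) stop("tree has zero total depth", call. = FALSE)
  ord <- order(rownames(C))
  C[ord, ord, drop = FALSE]
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal elements by `lambda`, interpolating between a
#' star phylogeny (`lambda = 0`, independent tips) and the full Brownian
#' structure (`lambda = 1`).
#'
#' @param C covariance matrix from [bm_covariance()].
#' @param lambda scalar in `[0, 1]`.
#' @return the transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]", call. = FALSE)
  }
  V <- lambda * C
  diag(V) <- diag(C)
  V
}
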