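#' VanRaden genomic relationship matrix
#'
#' Computes \eqn{K = Z Z^\top / (2 \sum_j p_j (1 - p_j))} where `Z` is the
#' column-centred dosage matrix (\eqn{M - 2p}) and the allele frequencies `p`
#' are estimated from the data. Under this scaling the mean diagonal of `K`
#' is close to 1 for a sample of unrelated genotypes in Hardy-Weinberg
#' proportions.
#'
#' @param markers a [MarkerSet] (see [read_markers()]) or a numeric dosage
#'   matrix (genotypes x loci, entries in \[0, 2\], no missing values).
#' @return symmetric PSD matrix with genotype row/column names.
#' @export
vanraden_grm <- function(markers) {
  M <- if (inherits(markers, "MarkerSet")) markers$dosage else as.matrix(markers)
  if (anyNA(M)) stop("dosage matrix contains missing values; run qc_markers() first")
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2) stop("need at least 2 polymorphic loci to build a GRM")
  M <- M[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(M, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  K <- tcrossprod(Z) / denom
  dimnames(K) <- list(rownames(M), rownames(M))
  K
}
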