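as_count_mat <- function(x) {
  if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
}

#' Median-of-ratios size factors
#'
#' DESeq-style library-depth estimates: for each sample, the median over
#' reference genes (genes with positive counts in every sample) of the ratio
#' of the sample's count to the gene's geometric mean across samples. Factors
#' are rescaled so their geometric mean is 1.
#'
#' @param x a [count_matrix()] or a plain count matrix (genes x samples).
#' @return Named positive numeric vector, one factor per sample, geometric
#'   mean 1.
#' @export
size_factors <- function(x) {
  m <- as_count_mat(x)
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref))
    stopf(paste("no gene has positive counts in every sample;",
                "median-of-ratios is undefined - use cpm() normalisation instead"))
  lg <- log(m[ref, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- exp(apply(lg - geo, 2L, stats::median))
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Counts per million
#'
#' `cpm[g, j] = counts[g, j] * 1e6 / library_size[j]` where the library size
#' is the column sum.
#'
#' @param x a [count_matrix()] or plain count matrix.
#' @return Numeric matrix of the same shape; every column sums to 1e6.
#' @export
cpm <- function(x) {
  m <- as_count_mat(x)
  tot <- colSums(m)
  if (any(tot == 0)) stopf("sample with zero total counts: CPM undefined")
  sweep(m, 2L, tot / 1e6, "/")
}

#' Fragments per kilobase per million mapped reads
#'
#' `fpkm[g, j] = counts[g, j] * 1e9 / (length_bp[g] * library_size[j])`.
#' Requires gene lengths on the count matrix.
#'
#' @param x a [count_matrix()] carrying `gene_lengths`.
#' @return Numeric matrix of FPKM values.
#' @export
fpkm <- function(x) {
  if (!inherits(x, "count_matrix") || is.null(x$gene_lengths))
    stopf("fpkm() needs a count_matrix with gene_lengths")
  m <- x$counts
  tot <- colSums(m)
  if (any(tot == 0)) stopf("sample with zero total counts: FPKM undefined")
  sweep(m / x$gene_lengths, 2L, tot / 1e9, "/")
}
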