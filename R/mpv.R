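#' Build mid-parent pseudo-samples
#'
#' Mid-parent expression values (MPV) are realised as in-silico
#' pseudo-replicates so that the same count-based test applies: replicate
#' `i` of parent A is paired with replicate `i` of parent C (sorted by
#' replicate index) and the MPV count is
#' `round((count_A / sf_A + count_C / sf_C) / 2)` with half-up rounding.
#' Pseudo-samples carry size factor 1 by construction.
#'
#' @param pair_mat pair-level count matrix from [pair_level_matrix()].
#' @param sheet sample sheet covering the matrix columns.
#' @param sf named size factors for the parent samples.
#' @return Integer matrix (pairs x replicates) with columns `MPV_1`, ...
#' @export
build_mpv <- function(pair_mat, sheet, sf) {
  pa <- group_samples(sheet, "PARENT_A")
  pc <- group_samples(sheet, "PARENT_C")
  if (length(pa) != length(pc))
    stopf("MPV needs equal replicate numbers in both parents (%d vs %d)",
          length(pa), length(pc))
  za <- sweep(pair_mat[, pa, drop = FALSE], 2L, sf[pa], "/")
  zc <- sweep(pair_mat[, pc, drop = FALSE], 2L, sf[pc], "/")
  mpv <- round_half_up((za + zc) / 2)
  storage.mode(mpv) <- "integer"
  colnames(mpv) <- paste0("MPV_", seq_along(pa))
  mpv
}

#' Test non-additive expression against the mid-parent value
#'
#' Compares the polyploid pair totals of one individual with the MPV
#' pseudo-replicates using the conditional NB exact test and BH adjustment.
#' A pair is non-additive iff `qvalue < alpha`.
#'
#' @param pair_mat pair-level count matrix ([pair_level_matrix()]).
#' @param sheet sample sheet.
#' @param individual polyploid individual to test.
#' @param sf named size factors for all samples of `pair_mat`.
#' @param alpha adjusted-p threshold (default 0.05).
#' @return List with `result` (a `de_result`-style data frame plus a logical
#'   `nonadditive` column), `fraction` (non-additive pairs over all pairs)
#'   and `n_pairs`.
#' @export
test_nonadditive <- function(pair_mat, sheet, individual, sf = NULL,
                             alpha = 0.05) {
  if (is.null(sf)) sf <- size_factors(pair_mat)
  mpv <- build_mpv(pair_mat, sheet, sf)
  if (ncol(mpv) < 2L) stopf("MPV needs >= 2 pseudo-replicates")
  poly <- group_samples(sheet, paste0("POLYPLOID/", individual))
  k1 <- mpv
  k2 <- pair_mat[, poly, drop = FALSE]
  sf1 <- rep(1, ncol(mpv))
  sf2 <- sf[poly]
  disp <- estimate_dispersion(k1, k2, sf1, sf2)
  res <- nb_test_table(k1, k2, sf1, sf2, disp)
  res$qvalue <- bh_adjust(res$pvalue)
  res$nonadditive <- res$qvalue < alpha
  list(result = res, fraction = mean(res$nonadditive), n_pairs = nrow(res))
}
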