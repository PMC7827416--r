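#' Method-of-moments dispersion with a local trend floor
#'
#' Counts are normalised by their size factors, per-group sample variances are
#' pooled by degrees of freedom, and the per-unit dispersion is the
#' moment estimate `max(0, (pooled_var - mean) / mean^2)` under the
#' parameterisation `variance = mean + dispersion * mean^2`. Because a
#' 2x3-replicate moment estimate is very noisy, each unit is floored at a
#' local trend: the running median of the moment estimates over the ~50
#' nearest units by mean expression. The final estimate is
#' `max(own, trend)`, which is deliberately conservative.
#'
#' @param k1,k2 integer count matrices (units x replicates) for the two groups.
#' @param sf1,sf2 size factors for the columns of `k1` and `k2`.
#' @return Numeric vector of per-unit dispersions (>= 0).
#' @export
estimate_dispersion <- function(k1, k2, sf1, sf2) {
  k1 <- as.matrix(k1); k2 <- as.matrix(k2)
  n1 <- ncol(k1); n2 <- ncol(k2)
  if (n1 < 2L && n2 < 2L)
    stopf("dispersion estimation needs >= 2 replicates in at least one group")
  z1 <- sweep(k1, 2L, sf1, "/")
  z2 <- sweep(k2, 2L, sf2, "/")
  m1 <- rowMeans(z1); m2 <- rowMeans(z2)
  v1 <- if (n1 >= 2L) row_var(z1) else rep(0, nrow(k1))
  v2 <- if (n2 >= 2L) row_var(z2) else rep(0, nrow(k2))
  df1 <- max(n1 - 1L, 0L); df2 <- max(n2 - 1L, 0L)
  pooled <- (df1 * v1 + df2 * v2) / (df1 + df2)
  mu <- (m1 + m2) / 2
  raw <- ifelse(mu > 0, pmax(0, (pooled - mu) / mu^2), 0)
  n <- length(raw)
  if (n >= 3L) {
    ord <- order(mu)
    k <- min(51L, if (n %% 2L == 1L) n else n - 1L)
    trend <- numeric(n)
    trend[ord] <- stats::runmed(raw[ord], k, endrule = "median")
    pmax(raw, trend)
  } else {
    raw
  }
}

# NB (or Poisson, when variance <= mean) density for a group sum with the
# given mean and variance.
sum_density <- function(x, M, V) {
  if (V <= M * (1 + 1e-12)) {
    stats::dpois(x, M)
  } else {
    stats::dnbinom(x, size = M^2 / (V - M), mu = M)
  }
}

#' Conditional negative-binomial exact test for two groups
#'
#' Tests whether two groups of replicated counts share a common normalised
#' mean. The test conditions on the grand total `K`: under the null the two
#' group sums have means proportional to the summed size factors, and the
#' two-sided p-value is the total conditional probability of all splits
#' `(a, K - a)` that are no more probable than the observed split
#' (minimum-likelihood method), capped at 1. Group-sum distributions are
#' negative binomial with moments accumulated over replicates
#' (`mu_j = q * s_j`, `var_j = mu_j + dispersion * mu_j^2`); at dispersion 0
#' the test reduces exactly to a conditional binomial test with success
#' probability `sum(sf2) / (sum(sf1) + sum(sf2))`. For totals above
#' `big_k` the conditional distribution is replaced by its normal
#' approximation (documented switch point).
#'
#' @param k1,k2 non-negative integer count vectors (one value per replicate).
#' @param sf1,sf2 positive size factors matching `k1`, `k2`.
#' @param dispersion NB dispersion (`variance = mean + dispersion * mean^2`).
#' @param big_k enumeration limit; larger totals use the normal approximation.
#' @return List with `pvalue` and `log2fc` (log2 of normalised group-2 over
#'   group-1 mean, pseudocount 1). A grand total of 0 returns
#'   `pvalue = 1, log2fc = 0` by convention.
#' @export
nb_exact_test <- function(k1, k2, sf1 = rep(1, length(k1)),
                          sf2 = rep(1, length(k2)), dispersion = 0,
                          big_k = 10000L) {
  if (any(k1 < 0) || any(k2 < 0) || !all(is_wholenumber(c(k1, k2))))
    stopf("counts must be non-negative integers")
  nm1 <- mean(k1 / sf1); nm2 <- mean(k2 / sf2)
  log2fc <- log2((nm2 + 1) / (nm1 + 1))
  T1 <- sum(k1); K <- T1 + sum(k2)
  if (K == 0) return(list(pvalue = 1, log2fc = 0))
  p <- nb_split_pvalue(T1, K, sf1, sf2, dispersion, big_k)
  list(pvalue = p, log2fc = log2fc)
}

# p-value for observed group-1 sum T1 of grand total K.
nb_split_pvalue <- function(T1, K, sf1, sf2, dispersion, big_k = 10000L) {
  S1 <- sum(sf1); S2 <- sum(sf2)
  q <- K / (S1 + S2)
  mu1 <- q * sf1; mu2 <- q * sf2
  M1 <- sum(mu1); M2 <- sum(mu2)
  V1 <- sum(mu1 + dispersion * mu1^2)
  V2 <- sum(mu2 + dispersion * mu2^2)
  if (K <= big_k) {
    a <- 0:K
    w <- sum_density(a, M1, V1) * sum_density(K - a, M2, V2)
    tot <- sum(w)
    if (tot <= 0) return(1)
    min(1, sum(w[w <= w[T1 + 1L] * (1 + 1e-7)]) / tot)
  } else {
    vc <- V1 * V2 / (V1 + V2)
    min(1, 2 * stats::pnorm(-abs(T1 - M1) / sqrt(vc)))
  }
}

# Vectorised test over the rows of two count matrices.
nb_test_table <- function(k1, k2, sf1, sf2, dispersions, big_k = 10000L) {
  k1 <- as.matrix(k1); k2 <- as.matrix(k2)
  n <- nrow(k1)
  nm1 <- rowMeans(sweep(k1, 2L, sf1, "/"))
  nm2 <- rowMeans(sweep(k2, 2L, sf2, "/"))
  T1 <- rowSums(k1); K <- T1 + rowSums(k2)
  pv <- numeric(n)
  for (i in seq_len(n)) {
    pv[i] <- if (K[i] == 0) 1 else
      nb_split_pvalue(T1[i], K[i], sf1, sf2, dispersions[i], big_k)
  }
  data.frame(unit_id = rownames(k1) %||% as.character(seq_len(n)),
             mean_A = nm1, mean_B = nm2,
             log2fc = ifelse(K == 0, 0, log2((nm2 + 1) / (nm1 + 1))),
             pvalue = pv, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1, returned in the input
#' order. Written out explicitly because the step-up primitive is part of the
#' package's differential-expression contract and is verified against an
#' independent implementation in the test suite.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stopf("p-values must lie in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues)
  q <- pvalues[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(1, q)
  out
}

parse_contrast <- function(contrast) {
  if (length(contrast) == 1L) contrast <- strsplit(contrast, ":", fixed = TRUE)[[1L]]
  if (length(contrast) != 2L)
    stopf("contrast must name two groups, e.g. 'PARENT_A:POLYPLOID/AACC1'")
  contrast
}

#' Call differential expression between two groups
#'
#' Runs the full pipeline for one contrast: size factors (median-of-ratios,
#' computed on the supplied matrix unless given), per-unit dispersion,
#' conditional NB exact test per unit, and Benjamini-Hochberg adjustment.
#' The ternary call is `UP_B` if `qvalue < alpha` and `log2fc > 0` (group 2
#' higher), `UP_A` if `qvalue < alpha` and `log2fc < 0`, otherwise `NS`
#' (strict inequality: `qvalue == alpha` is not significant).
#'
#' @param x a [count_matrix()], or a plain counts matrix (e.g. from
#'   [pair_level_matrix()]).
#' @param sheet a [as_sample_sheet()] data frame.
#' @param contrast two group labels (`"PARENT_A"`, `"PARENT_C"` or
#'   `"POLYPLOID/<individual>"`), as a length-2 vector or a single
#'   colon-separated string. Group 1 is the first label.
#' @param alpha significance threshold on the adjusted p-value (default 0.05).
#' @param sf optional named size factors for all samples of `x`; computed with
#'   [size_factors()] from the two groups' columns when omitted.
#' @return A `de_result` data frame: `unit_id`, `mean_A`, `mean_B` (normalised
#'   group means), `log2fc`, `pvalue`, `qvalue`, `call`.
#' @export
call_de <- function(x, sheet, contrast, alpha = 0.05, sf = NULL) {
  m <- as_count_mat(x)
  contrast <- parse_contrast(contrast)
  g1 <- group_samples(sheet, contrast[1L])
  g2 <- group_samples(sheet, contrast[2L])
  if (!all(c(g1, g2) %in% colnames(m)))
    stopf("configuration error: contrast samples missing from count matrix")
  if (is.null(sf)) sf <- size_factors(m[, c(g1, g2), drop = FALSE])
  k1 <- m[, g1, drop = FALSE]; k2 <- m[, g2, drop = FALSE]
  sf1 <- sf[g1]; sf2 <- sf[g2]
  disp <- estimate_dispersion(k1, k2, sf1, sf2)
  res <- nb_test_table(k1, k2, sf1, sf2, disp)
  res$qvalue <- bh_adjust(res$pvalue)
  res$call <- ifelse(res$qvalue < alpha & res$log2fc > 0, "UP_B",
                     ifelse(res$qvalue < alpha & res$log2fc < 0, "UP_A", "NS"))
  attr(res, "contrast") <- contrast
  attr(res, "alpha") <- alpha
  class(res) <- c("de_result", "data.frame")
  res
}
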