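# A bias state is derived from a DE result in which group 1 is the A copy
# and group 2 is the C copy: A_BIAS iff significant with the A copy higher.
bias_state_from <- function(qvalue, log2fc, alpha) {
  ifelse(qvalue < alpha & log2fc < 0, "A_BIAS",
         ifelse(qvalue < alpha & log2fc > 0, "C_BIAS", "NO_BIAS"))
}

# Shared test core for parental / hybrid homoeolog comparisons.
homoeolog_bias_test <- function(k1, k2, sf1, sf2, alpha) {
  disp <- estimate_dispersion(k1, k2, sf1, sf2)
  res <- nb_test_table(k1, k2, sf1, sf2, disp)
  res$qvalue <- bh_adjust(res$pvalue)
  res$state <- bias_state_from(res$qvalue, res$log2fc, alpha)
  names(res)[names(res) == "unit_id"] <- "pair_id"
  res
}

#' Parental homoeolog expression bias
#'
#' For every homoeolog pair, tests the A-gene counts in the parent-A samples
#' against the C-gene counts in the parent-C samples (NB exact test, BH over
#' pairs) and returns the ternary bias state.
#'
#' @param x a [count_matrix()] (gene level).
#' @param pairs a `pair_table`.
#' @param sheet sample sheet.
#' @param alpha adjusted-p threshold.
#' @param sf named per-sample size factors (typically from the pair-level
#'   matrix); computed from the parent columns when omitted.
#' @return Data frame `pair_id`, `mean_A`, `mean_B`, `log2fc`, `pvalue`,
#'   `qvalue`, `state` (`A_BIAS`/`NO_BIAS`/`C_BIAS`).
#' @export
parental_bias <- function(x, pairs, sheet, alpha = 0.05, sf = NULL) {
  m <- as_count_mat(x)
  pa <- group_samples(sheet, "PARENT_A")
  pc <- group_samples(sheet, "PARENT_C")
  k1 <- m[pairs$gene_A, pa, drop = FALSE]
  k2 <- m[pairs$gene_C, pc, drop = FALSE]
  rownames(k1) <- pairs$pair_id
  if (is.null(sf)) {
    both <- cbind(k1, k2)
    sf <- size_factors(both)
    names(sf) <- c(pa, pc)
  }
  homoeolog_bias_test(k1, k2, sf[pa], sf[pc], alpha)
}

#' Homoeolog expression bias within a polyploid individual
#'
#' Within each replicate of the individual, the A-homoeolog counts form group
#' 1 and the C-homoeolog counts group 2; both groups share that replicate's
#' size factor, so the test asks whether the two copies contribute equally to
#' the pair total. Optionally, gene lengths can correct the expected split
#' (a longer copy collects proportionally more reads at equal expression);
#' the default leaves counts uncorrected.
#'
#' @inheritParams parental_bias
#' @param individual polyploid individual.
#' @param use_lengths if `TRUE` (and `x` carries `gene_lengths`) scale each
#'   copy's effective size factor by its length in kb.
#' @return Data frame as in [parental_bias()].
#' @export
hybrid_bias <- function(x, pairs, sheet, individual, alpha = 0.05, sf = NULL,
                        use_lengths = FALSE) {
  m <- as_count_mat(x)
  poly <- group_samples(sheet, paste0("POLYPLOID/", individual))
  k1 <- m[pairs$gene_A, poly, drop = FALSE]
  k2 <- m[pairs$gene_C, poly, drop = FALSE]
  rownames(k1) <- pairs$pair_id
  if (is.null(sf)) sf <- stats::setNames(rep(1, length(poly)), poly)
  sf1 <- sf[poly]; sf2 <- sf[poly]
  if (use_lengths) {
    if (!inherits(x, "count_matrix") || is.null(x$gene_lengths))
      stopf("use_lengths = TRUE needs a count_matrix with gene_lengths")
    la <- x$gene_lengths[pairs$gene_A] / 1000
    lc <- x$gene_lengths[pairs$gene_C] / 1000
    # per-pair length correction: run pair-by-pair with scaled size factors
    n <- nrow(pairs)
    res <- vector("list", n)
    disp <- estimate_dispersion(k1, k2, sf1, sf2)
    pv <- numeric(n); l2 <- numeric(n); m1 <- numeric(n); m2 <- numeric(n)
    for (i in seq_len(n)) {
      r <- nb_exact_test(k1[i, ], k2[i, ], sf1 * la[i], sf2 * lc[i], disp[i])
      pv[i] <- r$pvalue; l2[i] <- r$log2fc
      m1[i] <- mean(k1[i, ] / (sf1 * la[i]))
      m2[i] <- mean(k2[i, ] / (sf2 * lc[i]))
    }
    out <- data.frame(pair_id = pairs$pair_id, mean_A = m1, mean_B = m2,
                      log2fc = l2, pvalue = pv, stringsAsFactors = FALSE)
    out$qvalue <- bh_adjust(out$pvalue)
    out$state <- bias_state_from(out$qvalue, out$log2fc, alpha)
    return(out)
  }
  homoeolog_bias_test(k1, k2, sf1, sf2, alpha)
}

#' Classify the bias transition from parents to polyploid
#'
#' Total mapping on the 9 combinations of parental and hybrid bias state:
#' equal states are the `PARENTAL_CONDITION`; a parental bias that vanishes is
#' `BIAS_LOST`; a bias arising from no parental bias is `NOVEL_BIAS_A` or
#' `NOVEL_BIAS_C` by its direction; an A-to-C (or C-to-A) flip is
#' `BIAS_REVERSED`.
#'
#' @param parent,hybrid character vectors of bias states
#'   (`A_BIAS`/`NO_BIAS`/`C_BIAS`); vectorised.
#' @return Character vector of transition patterns.
#' @export
classify_transition <- function(parent, hybrid) {
  states <- c("A_BIAS", "NO_BIAS", "C_BIAS")
  if (!all(parent %in% states) || !all(hybrid %in% states))
    stopf("bias states must be A_BIAS, NO_BIAS or C_BIAS")
  out <- character(length(parent))
  out[parent == hybrid] <- "PARENTAL_CONDITION"
  out[parent != "NO_BIAS" & hybrid == "NO_BIAS"] <- "BIAS_LOST"
  out[parent == "NO_BIAS" & hybrid == "A_BIAS"] <- "NOVEL_BIAS_A"
  out[parent == "NO_BIAS" & hybrid == "C_BIAS"] <- "NOVEL_BIAS_C"
  out[(parent == "A_BIAS" & hybrid == "C_BIAS") |
        (parent == "C_BIAS" & hybrid == "A_BIAS")] <- "BIAS_REVERSED"
  out
}

#' Summarise bias transitions and hybrid bias totals
#'
#' @param transitions character vector of transition patterns
#'   ([classify_transition()]).
#' @param hybrid_states character vector of hybrid bias states, same pairs.
#' @param n_pairs denominator for fractions (defaults to the vector length).
#' @param collapse_novel if `TRUE`, merge `NOVEL_BIAS_A` and `NOVEL_BIAS_C`
#'   into a single `NOVEL_BIAS` row.
#' @return List with `transitions` (counts/fractions per pattern) and
#'   `hybrid` (A/C bias counts and fractions).
#' @export
bias_summary <- function(transitions, hybrid_states,
                         n_pairs = length(transitions),
                         collapse_novel = FALSE) {
  lev <- c("PARENTAL_CONDITION", "BIAS_LOST", "NOVEL_BIAS_A", "NOVEL_BIAS_C",
           "BIAS_REVERSED")
  tc <- table(factor(transitions, levels = lev))
  tf <- data.frame(pattern = lev, count = as.integer(tc),
                   fraction = as.numeric(tc) / n_pairs,
                   stringsAsFactors = FALSE)
  if (collapse_novel) {
    novel <- tf$pattern %in% c("NOVEL_BIAS_A", "NOVEL_BIAS_C")
    merged <- data.frame(pattern = "NOVEL_BIAS", count = sum(tf$count[novel]),
                         fraction = sum(tf$fraction[novel]),
                         stringsAsFactors = FALSE)
    tf <- rbind(tf[!novel, ], merged)
    rownames(tf) <- NULL
  }
  hs <- table(factor(hybrid_states, levels = c("A_BIAS", "NO_BIAS", "C_BIAS")))
  list(transitions = tf,
       hybrid = data.frame(state = names(hs), count = as.integer(hs),
                           fraction = as.numeric(hs) / n_pairs,
                           stringsAsFactors = FALSE))
}
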