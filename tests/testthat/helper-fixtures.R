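# Small in-code fixtures shared across tests.

toy_sheet <- function(reps = 2L, individuals = "AACC1") {
  df <- data.frame(
    sample_id = c(paste0("PA_", seq_len(reps)), paste0("PC_", seq_len(reps)),
                  unlist(lapply(individuals,
                                function(i) paste0(i, "_", seq_len(reps))))),
    genotype = c(rep("PARENT_A", reps), rep("PARENT_C", reps),
                 rep("POLYPLOID", reps * length(individuals))),
    individual = c(rep("", 2L * reps), rep(individuals, each = reps)),
    replicate = c(seq_len(reps), seq_len(reps),
                  rep(seq_len(reps), length(individuals))),
    stringsAsFactors = FALSE)
  as_sample_sheet(df)
}

toy_counts <- function(sheet, n_pairs = 2L, fill = NULL, lengths = NULL) {
  genes <- c(sprintf("A%03d", seq_len(n_pairs)), sprintf("C%03d", seq_len(n_pairs)))
  m <- if (is.null(fill)) {
    matrix(seq_len(2L * n_pairs * nrow(sheet)), 2L * n_pairs,
           dimnames = list(genes, sheet$sample_id))
  } else {
    matrix(fill, 2L * n_pairs, nrow(sheet),
           dimnames = list(genes, sheet$sample_id))
  }
  count_matrix(m, rep(c("A", "C"), each = n_pairs), lengths)
}

toy_pairs <- function(n_pairs = 2L) {
  as_pair_table(data.frame(
    pair_id = sprintf("HP%03d", seq_len(n_pairs)),
    gene_A = sprintf("A%03d", seq_len(n_pairs)),
    gene_C = sprintf("C%03d", seq_len(n_pairs)),
    identity_pct = rep(95, n_pairs), evalue = rep(1e-20, n_pairs),
    stringsAsFactors = FALSE))
}

# Brute-force BH step-up, kept deliberately naive and independent of the
# package implementation: q_i = min over ranks j >= rank_i of p_(j) * m / j.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Independent two-sided conditional binomial p-value (minimum likelihood).
brute_binom_p <- function(a_obs, K, prob1) {
  w <- dbinom(0:K, K, prob1)
  sum(w[w <= w[a_obs + 1L] * (1 + 1e-7)]) / sum(w)
}
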