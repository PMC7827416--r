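test_that("transition classification is total on the 9 state pairs", {
  states <- c("A_BIAS", "NO_BIAS", "C_BIAS")
  combos <- expand.grid(parent = states, hybrid = states,
                        stringsAsFactors = FALSE)
  tr <- classify_transition(combos$parent, combos$hybrid)
  expect_false(any(tr == ""))
  expect_identical(classify_transition("A_BIAS", "A_BIAS"), "PARENTAL_CONDITION")
  expect_identical(classify_transition("NO_BIAS", "NO_BIAS"), "PARENTAL_CONDITION")
  expect_identical(classify_transition("C_BIAS", "NO_BIAS"), "BIAS_LOST")
  expect_identical(classify_transition("NO_BIAS", "A_BIAS"), "NOVEL_BIAS_A")
  expect_identical(classify_transition("NO_BIAS", "C_BIAS"), "NOVEL_BIAS_C")
  expect_identical(classify_transition("A_BIAS", "C_BIAS"), "BIAS_REVERSED")
  expect_identical(classify_transition("C_BIAS", "A_BIAS"), "BIAS_REVERSED")
  # enumeration cell counts
  s <- bias_summary(tr, combos$hybrid, n_pairs = 9L)
  got <- setNames(s$transitions$count, s$transitions$pattern)
  expect_identical(got[["PARENTAL_CONDITION"]], 3L)
  expect_identical(got[["BIAS_LOST"]], 2L)
  expect_identical(got[["NOVEL_BIAS_A"]], 1L)
  expect_identical(got[["NOVEL_BIAS_C"]], 1L)
  expect_identical(got[["BIAS_REVERSED"]], 2L)
  expect_equal(sum(s$transitions$fraction), 1)
  s2 <- bias_summary(tr, combos$hybrid, n_pairs = 9L, collapse_novel = TRUE)
  expect_identical(s2$transitions$count[s2$transitions$pattern == "NOVEL_BIAS"], 2L)
})

test_that("hybrid bias calls symmetric and one-sided pairs correctly", {
  sheet <- toy_sheet(reps = 3L)
  pairs <- toy_pairs(1L)
  poly <- sheet$sample_id[sheet$genotype == "POLYPLOID"]
  base <- matrix(50L, 2, nrow(sheet),
                 dimnames = list(c("A001", "C001"), sheet$sample_id))
  cm <- count_matrix(base, c("A", "C"))
  out <- hybrid_bias(cm, pairs, sheet, "AACC1")
  expect_identical(out$state, "NO_BIAS")

  m <- base
  m["A001", poly] <- 0L
  m["C001", poly] <- c(100L, 120L, 90L)
  out <- hybrid_bias(count_matrix(m, c("A", "C")), pairs, sheet, "AACC1")
  expect_identical(out$state, "C_BIAS")
})

test_that("parental bias recovers planted direction and respects alpha = 0", {
  set.seed(13)
  sheet <- toy_sheet(reps = 3L)
  n <- 300
  genes <- c(sprintf("A%03d", 1:n), sprintf("C%03d", 1:n))
  pa_mu <- c(rep(200 * 16, n / 2), rep(200, n / 2))  # half planted A-biased
  m <- matrix(0L, 2 * n, nrow(sheet), dimnames = list(genes, sheet$sample_id))
  pa_cols <- sheet$genotype == "PARENT_A"
  pc_cols <- sheet$genotype == "PARENT_C"
  m[1:n, pa_cols] <- rnbinom(3 * n, mu = pa_mu, size = 20)
  m[n + 1:n, pc_cols] <- rnbinom(3 * n, mu = 200, size = 20)
  m[, sheet$genotype == "POLYPLOID"] <- rpois(2 * n * sum(!pa_cols & !pc_cols), 100)
  cm <- count_matrix(m, rep(c("A", "C"), each = n))
  pairs <- toy_pairs(n)
  sf <- setNames(rep(1, nrow(sheet)), sheet$sample_id)
  out <- parental_bias(cm, pairs, sheet, sf = sf)
  expect_gte(mean(out$state[1:(n / 2)] == "A_BIAS"), 0.9)
  out0 <- parental_bias(cm, pairs, sheet, alpha = 0, sf = sf)
  expect_true(all(out0$state == "NO_BIAS"))
})

test_that("swapping subgenome labels mirrors every bias result", {
  sim <- simulate_allopolyploid(sim_config(n_pairs = 300, n_individuals = 1,
                                           seed = 99))
  pm <- pair_level_matrix(sim$counts, sim$pairs, sim$sheet)
  sf <- size_factors(pm)
  hb <- hybrid_bias(sim$counts, sim$pairs, sim$sheet, "AACC1", sf = sf)
  swapped_pairs <- sim$pairs
  swapped_pairs$gene_A <- sim$pairs$gene_C
  swapped_pairs$gene_C <- sim$pairs$gene_A
  hb_sw <- hybrid_bias(sim$counts, swapped_pairs, sim$sheet, "AACC1", sf = sf)
  flip <- c(A_BIAS = "C_BIAS", NO_BIAS = "NO_BIAS", C_BIAS = "A_BIAS")
  expect_identical(unname(flip[hb$state]), hb_sw$state)

  # parental comparison: swap the parent roles together with the gene roles
  pb <- parental_bias(sim$counts, sim$pairs, sim$sheet, sf = sf)
  sheet_sw <- sim$sheet
  sheet_sw$genotype[sim$sheet$genotype == "PARENT_A"] <- "PARENT_C"
  sheet_sw$genotype[sim$sheet$genotype == "PARENT_C"] <- "PARENT_A"
  class(sheet_sw) <- class(sim$sheet)
  pb_sw <- parental_bias(sim$counts, swapped_pairs, sheet_sw, sf = sf)
  expect_identical(unname(flip[pb$state]), pb_sw$state)

  # transition counts: PARENTAL_CONDITION / LOST / REVERSED invariant,
  # the novel directions swap
  tr <- table(classify_transition(pb$state, hb$state))
  tr_sw <- table(classify_transition(pb_sw$state, hb_sw$state))
  for (inv in c("PARENTAL_CONDITION", "BIAS_LOST", "BIAS_REVERSED"))
    expect_identical(tr[inv], tr_sw[inv])
  expect_equal(unname(tr["NOVEL_BIAS_A"]), unname(tr_sw["NOVEL_BIAS_C"]))
})
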