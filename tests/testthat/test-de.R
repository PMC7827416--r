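test_that("exact test matches closed-form conditional binomial cases", {
  # all-or-nothing split of K = 10 under equal sizes: p = 2 * (1/2)^10
  r <- nb_exact_test(c(0, 0), c(5, 5), c(1, 1), c(1, 1), dispersion = 0)
  expect_equal(r$pvalue, 2 / 1024)
  # K = 6, split (1, 5): splits {0,1,5,6} are no more likely -> 14/64
  r <- nb_exact_test(c(1, 0), c(2, 3), c(1, 1), c(1, 1), dispersion = 0)
  expect_equal(r$pvalue, 14 / 64)
  # identical groups: symmetric mode -> p = 1, log2fc = 0
  r <- nb_exact_test(c(4, 6), c(4, 6), c(1, 1), c(1, 1), dispersion = 0.1)
  expect_equal(r$pvalue, 1)
  expect_equal(r$log2fc, 0)
  # grand total zero: convention
  r <- nb_exact_test(c(0, 0), c(0, 0))
  expect_equal(r$pvalue, 1)
  expect_equal(r$log2fc, 0)
})

test_that("unequal size factors shift the conditional success probability", {
  # dispersion 0 with summed sizes 2 vs 4: conditional Binomial(K, 1/3)
  sf1 <- c(1, 1); sf2 <- c(2, 2)
  for (a in c(0, 3, 7, 12)) {
    r <- nb_exact_test(c(a, 0), c(6, 6), sf1, sf2, dispersion = 0)
    expect_equal(r$pvalue, brute_binom_p(a, a + 12, 1 / 3), tolerance = 1e-12)
  }
})

test_that("BH step-up matches closed forms and stats::p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  for (i in 1:25) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_adjust(p), stats::p.adjust(p, method = "BH"))
  }
  # permutation changes nothing but the order
  p <- runif(50)
  perm <- sample(50)
  expect_equal(sort(bh_adjust(p)), sort(bh_adjust(p[perm])))
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("qvalues dominate pvalues and lie in the unit interval", {
  set.seed(4)
  p <- c(runif(100)^2, 0, 1)
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-12))
  expect_true(all(q >= 0 & q <= 1))
})

test_that("moment dispersion is consistent on simulated truth", {
  set.seed(9)
  n <- 10000
  k1 <- matrix(rpois(3 * n, 1000), n)
  k2 <- matrix(rpois(3 * n, 1000), n)
  d <- estimate_dispersion(k1, k2, rep(1, 3), rep(1, 3))
  expect_lte(median(d), 0.01)

  k1 <- matrix(rnbinom(3 * n, mu = 500, size = 1 / 0.2), n)
  k2 <- matrix(rnbinom(3 * n, mu = 500, size = 1 / 0.2), n)
  d <- estimate_dispersion(k1, k2, rep(1, 3), rep(1, 3))
  expect_gte(median(d), 0.1)
  expect_lte(median(d), 0.3)

  # variance-free replicates floor at zero
  k <- matrix(7L, 5, 3)
  expect_equal(estimate_dispersion(k, k, rep(1, 3), rep(1, 3)), rep(0, 5))
  expect_error(estimate_dispersion(matrix(1, 2, 1), matrix(1, 2, 1), 1, 1),
               "replicates")
})

test_that("call_de recovers strong planted effects and respects the strict threshold", {
  set.seed(21)
  n <- 600
  sheet <- as_sample_sheet(data.frame(
    sample_id = c("PA_1", "PA_2", "PA_3", "PC_1", "PC_2", "PC_3"),
    genotype = rep(c("PARENT_A", "PARENT_C"), each = 3),
    individual = "", replicate = rep(1:3, 2)))
  mu1 <- rep(200, n)
  # balanced planted effects: a sixth 16-fold up in C, a sixth 16-fold down
  mu2 <- rep(200, n)
  up <- 1:(n / 6); down <- (n / 6 + 1):(n / 3)
  mu2[up] <- 200 * 16; mu2[down] <- 200 / 16
  m <- cbind(matrix(rnbinom(3 * n, mu = mu1, size = 20), n),
             matrix(rnbinom(3 * n, mu = mu2, size = 20), n))
  dimnames(m) <- list(sprintf("g%03d", 1:n), sheet$sample_id)
  de <- call_de(m, sheet, c("PARENT_A", "PARENT_C"))
  expect_gte(mean(de$call[up] == "UP_B"), 0.95)
  expect_gte(mean(de$call[down] == "UP_A"), 0.95)
  # boundary convention: a pair whose qvalue equals alpha is not significant
  de2 <- call_de(m, sheet, c("PARENT_A", "PARENT_C"),
                 alpha = de$qvalue[de$qvalue > 0.1][1])
  expect_identical(de2$call[match(de$unit_id[de$qvalue > 0.1][1], de2$unit_id)],
                   "NS")
})
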