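test_that("simulation is reproducible and validates its configuration", {
  cfg <- sim_config(n_pairs = 500, n_individuals = 2, seed = 5)
  s1 <- simulate_allopolyploid(cfg)
  s2 <- simulate_allopolyploid(cfg)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$depths, s2$depths)
  expect_error(sim_config(class_proportions = c(CONSERVED = 1)), "named over")
  expect_error(sim_config(effect_log2fc = -1), ">= 0")
  expect_error(sim_config(n_pairs = 0), "positive")
})

test_that("planted class frequencies follow the configured proportions", {
  cfg <- sim_config(n_pairs = 20000, n_individuals = 1, seed = 6)
  sim <- simulate_allopolyploid(cfg)
  phat <- prop.table(table(sim$truth$class))
  for (k in names(cfg$class_proportions)) {
    p <- cfg$class_proportions[[k]]
    tol <- 4 * sqrt(p * (1 - p) / cfg$n_pairs)
    expect_lt(abs(phat[[k]] - p), tol + 1e-12)
  }
})

test_that("conserved-only simulation reproduces the planted means", {
  cfg <- sim_config(n_pairs = 1000, n_individuals = 1, seed = 7,
                    class_proportions = c(CONSERVED = 1, ADDITIVE = 0,
                                          ELD_A = 0, ELD_C = 0, TRANS_UP = 0,
                                          TRANS_DOWN = 0, NONADDITIVE_ONLY = 0,
                                          SILENCED_A = 0, SILENCED_C = 0,
                                          NOVEL = 0),
                    effect_log2fc = 0, depth_range = c(1, 1))
  sim <- simulate_allopolyploid(cfg)
  pm <- pair_level_matrix(sim$counts, sim$pairs, sim$sheet)
  # all groups share the planted baseline mean; group means agree within 5%
  grand <- mean(pm)
  for (g in c("PARENT_A", "PARENT_C", "POLYPLOID")) {
    cols <- sim$sheet$sample_id[sim$sheet$genotype == g]
    expect_lt(abs(mean(pm[, cols]) - grand) / grand, 0.05)
  }
})

test_that("zero dispersion gives Poisson-like counts", {
  cfg <- sim_config(n_pairs = 1000, n_individuals = 1, seed = 8,
                    dispersion = 0, depth_range = c(1, 1),
                    baseline_meanlog = log(1000), baseline_sdlog = 0)
  sim <- simulate_allopolyploid(cfg)
  pa <- sim$sheet$sample_id[sim$sheet$genotype == "PARENT_A"]
  k <- sim$counts$counts[sprintf("A%06d",
         which(sim$truth$class == "CONSERVED")), pa]
  ratio <- apply(k, 1, var) / rowMeans(k)
  expect_lt(abs(mean(ratio) - 1), 0.15)
})

test_that("recovery scoring handles perfect, empty and partial results", {
  sim <- simulate_allopolyploid(sim_config(n_pairs = 200, n_individuals = 1,
                                           seed = 9))
  perfect <- data.frame(pair_id = sim$truth$pair_id, individual = "AACC1",
                        roman = sim$truth$roman_expected,
                        pattern = sim$truth$pattern_expected,
                        stringsAsFactors = FALSE)
  ev <- evaluate_recovery(sim$truth, perfect)
  expect_true(all(ev$per_class$recall[ev$per_class$planted > 0] == 1))
  expect_identical(sum(ev$confusion) - sum(diag(ev$confusion)), 0L)

  ev0 <- evaluate_recovery(sim$truth, perfect[0, ])
  expect_true(all(ev0$per_class$recall == 0))
  expect_true(all(ev0$per_class$precision == 0))

  # flipping a tenth of the conserved calls drops exactly that much recall
  cons <- perfect[perfect$pattern == "CONSERVED", ]
  k <- floor(nrow(cons) / 10)
  cons$pattern[seq_len(k)] <- "ADDITIVE"
  ev9 <- evaluate_recovery(sim$truth, cons)
  got <- ev9$per_class
  expect_identical(got$recovered[got$pattern == "CONSERVED"],
                   nrow(cons) - as.integer(k))
  expect_error(evaluate_recovery(sim$truth,
                                 data.frame(pair_id = "nope",
                                            pattern = "CONSERVED")),
               "absent")
})

test_that("threshold classes are planted with working margins", {
  sim <- simulate_allopolyploid(sim_config(n_pairs = 3000, n_individuals = 2,
                                           seed = 10))
  cpm_m <- cpm(sim$counts)
  sheet <- sim$sheet
  pa <- sheet$sample_id[sheet$genotype == "PARENT_A"]
  po <- sheet$sample_id[sheet$individual == "AACC1"]
  sa <- which(sim$truth$silenced_A)
  expect_true(all(cpm_m[sprintf("A%06d", sa), pa] > 10))
  expect_true(all(sim$counts$counts[sprintf("A%06d", sa), po] == 0))
  nv <- which(sim$truth$novel_A)
  expect_true(all(cpm_m[sprintf("A%06d", nv), po] > 10))
  expect_true(all(sim$counts$counts[sprintf("A%06d", nv), c(pa)] == 0))
})
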