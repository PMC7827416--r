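all_triples <- expand.grid(d_ac = c("A<C", "A=C", "A>C"),
                           d_ta = c("T<A", "T=A", "T>A"),
                           d_tc = c("T<C", "T=C", "T>C"),
                           stringsAsFactors = FALSE)

test_that("the triple classifier is total and matches the canonical cases", {
  roman <- classify_triple(all_triples$d_ac, all_triples$d_ta, all_triples$d_tc)
  expect_false(anyNA(roman))
  expect_identical(length(roman), 27L)
  counts <- table(roman)
  expect_identical(as.integer(counts[as.character(as.roman(1:12))]),
                   rep(1L, 12))
  expect_identical(as.integer(counts["CONSERVED"]), 1L)
  expect_identical(as.integer(counts["AMBIGUOUS"]), 14L)

  expect_identical(classify_triple("A<C", "T=A", "T<C"), "IV")
  expect_identical(eld_pattern("IV"), "ELD_A")
  expect_identical(classify_triple("A=C", "T=A", "T=C"), "CONSERVED")
  expect_identical(classify_triple("A=C", "T>A", "T>C"), "V")
  expect_identical(eld_pattern("V"), "TRANS_UP")
  expect_error(classify_triple("A<C", "bogus", "T<C"), "relation")
})

test_that("pattern groups are exactly characterised by their relation structure", {
  roman <- classify_triple(all_triples$d_ac, all_triples$d_ta, all_triples$d_tc)
  pattern <- eld_pattern(roman)
  with(all_triples, {
    eq_ta <- d_ta == "T=A"; eq_tc <- d_tc == "T=C"; eq_ac <- d_ac == "A=C"
    up_ta <- d_ta == "T>A"; up_tc <- d_tc == "T>C"
    dn_ta <- d_ta == "T<A"; dn_tc <- d_tc == "T<C"
    expect_identical(pattern == "ELD_A", eq_ta & !eq_tc & !eq_ac &
                       ((d_ac == "A<C") == (d_tc == "T<C")))
    expect_identical(pattern == "ELD_C", eq_tc & !eq_ta & !eq_ac &
                       ((d_ac == "A<C") == (d_ta == "T>A")))
    expect_identical(pattern == "TRANS_UP", up_ta & up_tc)
    expect_identical(pattern == "TRANS_DOWN", dn_ta & dn_tc)
    # additive: total strictly between two differing parents
    expect_identical(pattern == "ADDITIVE",
                     (d_ac == "A<C" & up_ta & dn_tc) |
                       (d_ac == "A>C" & dn_ta & up_tc))
    expect_identical(pattern == "CONSERVED", eq_ac & eq_ta & eq_tc)
  })
})

test_that("pair-level matrix projects parents and sums polyploids", {
  sheet <- toy_sheet()
  cm <- toy_counts(sheet, n_pairs = 2L)
  pairs <- toy_pairs(2L)
  pm <- pair_level_matrix(cm, pairs, sheet)
  pa <- sheet$sample_id[sheet$genotype == "PARENT_A"][1]
  pc <- sheet$sample_id[sheet$genotype == "PARENT_C"][1]
  po <- sheet$sample_id[sheet$genotype == "POLYPLOID"][1]
  expect_identical(pm[, pa], cm$counts[c("A001", "A002"), pa],
                   ignore_attr = TRUE)
  expect_equal(unname(pm[, pc]), unname(cm$counts[c("C001", "C002"), pc]))
  expect_equal(unname(pm[, po]),
               unname(cm$counts[c("A001", "A002"), po] +
                        cm$counts[c("C001", "C002"), po]))
  expect_identical(nrow(pair_level_matrix(cm, toy_pairs(0L), sheet)), 0L)
  bad <- toy_pairs(2L); bad$gene_C[2] <- "C999"
  expect_error(pair_level_matrix(cm, bad, sheet), "HP002")
})

test_that("per-individual classification assembles the three DE calls", {
  de <- function(calls) data.frame(unit_id = paste0("HP", seq_along(calls)),
                                   call = calls, stringsAsFactors = FALSE)
  # all NS -> conserved
  out <- classify_individual(de("NS"), de("NS"), de("NS"), "AACC1")
  expect_identical(out$roman, "CONSERVED")
  # A<C (UP_B in AC), T>A (UP_B in TA), T=C -> II / ELD_C
  out <- classify_individual(de("UP_B"), de("NS"), de("UP_B"), "AACC1")
  expect_identical(out$roman, "II")
  expect_identical(out$pattern, "ELD_C")
  expect_error(classify_individual(de(c("NS", "NS")), de("NS"), de("NS")),
               "same pair ids")
})

test_that("pattern summaries partition over the full pair universe", {
  assign <- data.frame(pair_id = sprintf("HP%03d", 1:100),
                       individual = "AACC1",
                       roman = c(rep("I", 8), rep("XII", 5), rep("V", 10),
                                 rep("CONSERVED", 77)),
                       stringsAsFactors = FALSE)
  assign$pattern <- eld_pattern(assign$roman)
  s <- pattern_summary(assign, 100L)
  expect_equal(s$pattern$fraction[s$pattern$pattern == "ADDITIVE"], 0.13)
  expect_identical(sum(s$roman$count), 100L)
  expect_identical(sum(s$pattern$count), 100L)
  s0 <- pattern_summary(assign[0, ], 100L)
  expect_true(all(s0$pattern$count == 0L))
})
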