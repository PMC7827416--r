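# Canonical 12-category table. The three ternary relations are
#   d_AC: parent A vs parent C       in {"A<C", "A=C", "A>C"}
#   d_TA: polyploid total vs parent A in {"T<A", "T=A", "T>A"}
#   d_TC: polyploid total vs parent C in {"T<C", "T=C", "T>C"}
# The pattern groups are fixed by the biology (additive = total strictly
# between differing parents; ELD = total equal to one parent, different from
# the other; transgressive = total beyond both parents); the roman numbering
# within a group is the package's canonical convention.
eld_table <- local({
  def <- rbind(
    c("A=C", "T=A", "T=C", "CONSERVED", "CONSERVED"),
    c("A<C", "T>A", "T<C", "I",    "ADDITIVE"),
    c("A>C", "T<A", "T>C", "XII",  "ADDITIVE"),
    c("A<C", "T=A", "T<C", "IV",   "ELD_A"),
    c("A>C", "T=A", "T>C", "IX",   "ELD_A"),
    c("A<C", "T>A", "T=C", "II",   "ELD_C"),
    c("A>C", "T<A", "T=C", "XI",   "ELD_C"),
    c("A=C", "T>A", "T>C", "V",    "TRANS_UP"),
    c("A<C", "T>A", "T>C", "VI",   "TRANS_UP"),
    c("A>C", "T>A", "T>C", "VIII", "TRANS_UP"),
    c("A=C", "T<A", "T<C", "VII",  "TRANS_DOWN"),
    c("A<C", "T<A", "T<C", "III",  "TRANS_DOWN"),
    c("A>C", "T<A", "T<C", "X",    "TRANS_DOWN"))
  all27 <- expand.grid(d_AC = c("A<C", "A=C", "A>C"),
                       d_TA = c("T<A", "T=A", "T>A"),
                       d_TC = c("T<C", "T=C", "T>C"),
                       stringsAsFactors = FALSE)
  key <- paste(all27$d_AC, all27$d_TA, all27$d_TC)
  defkey <- paste(def[, 1L], def[, 2L], def[, 3L])
  idx <- match(key, defkey)
  all27$roman <- ifelse(is.na(idx), "AMBIGUOUS", def[idx, 4L])
  all27$pattern <- ifelse(is.na(idx), "AMBIGUOUS", def[idx, 5L])
  all27
})

roman_to_pattern <- stats::setNames(eld_table$pattern, eld_table$roman)[
  !duplicated(eld_table$roman)]

#' Classify one ternary triple into the 12 expression categories
#'
#' Total, deterministic mapping of the 27 possible combinations of the three
#' ternary differential-expression relations onto the twelve roman categories
#' plus `CONSERVED` (all three relations equal) and `AMBIGUOUS` (the 14
#' combinations that fit no category, e.g. total equal to both parents while
#' the parents differ).
#'
#' @param d_ac relation of parent A vs parent C: `"A<C"`, `"A=C"` or `"A>C"`.
#' @param d_ta relation of the polyploid pair total vs parent A: `"T<A"`,
#'   `"T=A"` or `"T>A"`.
#' @param d_tc relation of the total vs parent C: `"T<C"`, `"T=C"` or `"T>C"`.
#' @return Character vector of roman categories (`I`..`XII`, `CONSERVED`,
#'   `AMBIGUOUS`); vectorised over the three arguments.
#' @seealso [eld_pattern()] for the category-to-pattern grouping.
#' @export
classify_triple <- function(d_ac, d_ta, d_tc) {
  ok_ac <- d_ac %in% c("A<C", "A=C", "A>C")
  ok_ta <- d_ta %in% c("T<A", "T=A", "T>A")
  ok_tc <- d_tc %in% c("T<C", "T=C", "T>C")
  if (!all(ok_ac & ok_ta & ok_tc)) stopf("invalid ternary relation code")
  key <- paste(d_ac, d_ta, d_tc)
  tabkey <- paste(eld_table$d_AC, eld_table$d_TA, eld_table$d_TC)
  eld_table$roman[match(key, tabkey)]
}

#' Map roman categories to combined expression patterns
#'
#' `I, XII -> ADDITIVE`; `IV, IX -> ELD_A`; `II, XI -> ELD_C`;
#' `V, VI, VIII -> TRANS_UP`; `III, VII, X -> TRANS_DOWN`; `CONSERVED` and
#' `AMBIGUOUS` map to themselves.
#'
#' @param roman character vector of roman categories.
#' @return Character vector of patterns.
#' @export
eld_pattern <- function(roman) {
  out <- unname(roman_to_pattern[roman])
  if (any(is.na(out))) stopf("unknown roman category '%s'", roman[is.na(out)][1L])
  out
}

#' Collapse gene-level counts to homoeolog-pair level
#'
#' Builds the pair-by-sample matrix on which the polyploid total can be
#' compared with each parent: parent-A samples take the A-gene counts,
#' parent-C samples the C-gene counts, and polyploid samples the sum of the
#' two homoeolog counts (the pair total).
#'
#' @param x a [count_matrix()].
#' @param pairs a [as_pair_table()] data frame; both genes of every pair must
#'   be present in `x`.
#' @param sheet a [as_sample_sheet()] data frame covering the samples of `x`.
#' @return Integer matrix (pairs x samples) with `pair_id` rownames.
#' @export
pair_level_matrix <- function(x, pairs, sheet) {
  m <- as_count_mat(x)
  miss_a <- setdiff(pairs$gene_A, rownames(m))
  miss_c <- setdiff(pairs$gene_C, rownames(m))
  if (length(miss_a) || length(miss_c)) {
    bad <- c(miss_a, miss_c)[1L]
    pid <- pairs$pair_id[pairs$gene_A == bad | pairs$gene_C == bad][1L]
    stopf("gene '%s' of pair '%s' missing from count matrix", bad, pid)
  }
  samples <- sheet$sample_id
  if (!all(samples %in% colnames(m)))
    stopf("configuration error: sheet sample missing from count matrix")
  out <- matrix(0L, nrow(pairs), length(samples),
                dimnames = list(pairs$pair_id, samples))
  ka <- m[pairs$gene_A, samples, drop = FALSE]
  kc <- m[pairs$gene_C, samples, drop = FALSE]
  geno <- sheet$genotype[match(samples, sheet$sample_id)]
  out[, geno == "PARENT_A"] <- ka[, geno == "PARENT_A"]
  out[, geno == "PARENT_C"] <- kc[, geno == "PARENT_C"]
  out[, geno == "POLYPLOID"] <- ka[, geno == "POLYPLOID"] +
    kc[, geno == "POLYPLOID"]
  out
}

# Translate DE calls into ternary relations; `lo`/`hi` are the codes for
# group 1 resp. group 2 higher, `eq` for no significant difference.
ternary_from_call <- function(call, lo, eq, hi) {
  ifelse(call == "UP_B", hi, ifelse(call == "UP_A", lo, eq))
}

#' Assign 12-category ELD classes for one polyploid individual
#'
#' Combines three `de_result` tables into per-pair ternary relations and
#' applies [classify_triple()]. Contrast orientation is fixed: `de_ta` must be
#' parent A (group 1) vs the polyploid total (group 2), `de_tc` parent C vs
#' the total, and `de_ac` parent A vs parent C.
#'
#' @param de_ta,de_tc,de_ac `de_result` tables from [call_de()] over the same
#'   pair ids.
#' @param individual label of the polyploid individual being classified.
#' @return A `category_assignment` data frame: `pair_id`, `individual`,
#'   `roman`, `pattern`.
#' @export
classify_individual <- function(de_ta, de_tc, de_ac, individual = "") {
  ids <- de_ac$unit_id
  if (!setequal(ids, de_ta$unit_id) || !setequal(ids, de_tc$unit_id))
    stopf("the three DE tables must cover the same pair ids")
  ta <- de_ta[match(ids, de_ta$unit_id), ]
  tc <- de_tc[match(ids, de_tc$unit_id), ]
  d_ac <- ternary_from_call(de_ac$call, "A>C", "A=C", "A<C")
  d_ta <- ternary_from_call(ta$call, "T<A", "T=A", "T>A")
  d_tc <- ternary_from_call(tc$call, "T<C", "T=C", "T>C")
  roman <- classify_triple(d_ac, d_ta, d_tc)
  out <- data.frame(pair_id = ids, individual = individual, roman = roman,
                    pattern = eld_pattern(roman), stringsAsFactors = FALSE)
  class(out) <- c("category_assignment", "data.frame")
  out
}

#' Summarise category and pattern frequencies
#'
#' Counts and fractions per roman category and per combined pattern. The
#' fractions use the full homoeolog-pair count as denominator, so categories
#' absent from `assignments` contribute zero.
#'
#' @param assignments a `category_assignment` data frame.
#' @param n_pairs denominator: total number of homoeolog pairs.
#' @return List with data frames `roman` and `pattern` (columns `count`,
#'   `fraction`).
#' @export
pattern_summary <- function(assignments, n_pairs) {
  romans <- c(as.character(as.roman(1:12)), "CONSERVED", "AMBIGUOUS")
  patterns <- c("ADDITIVE", "ELD_A", "ELD_C", "TRANS_UP", "TRANS_DOWN",
                "CONSERVED", "AMBIGUOUS")
  rc <- table(factor(assignments$roman, levels = romans))
  pc <- table(factor(assignments$pattern, levels = patterns))
  list(roman = data.frame(roman = romans, count = as.integer(rc),
                          fraction = as.numeric(rc) / n_pairs,
                          stringsAsFactors = FALSE),
       pattern = data.frame(pattern = patterns, count = as.integer(pc),
                            fraction = as.numeric(pc) / n_pairs,
                            stringsAsFactors = FALSE))
}
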