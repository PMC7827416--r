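#' Novel-expression rule for one homoeolog
#'
#' A homoeolog shows novel expression in a polyploid individual iff *both*
#' parental species have zero raw counts for the pair (the A gene in every
#' parent-A replicate and the C gene in every parent-C replicate) while the
#' polyploid shows more than `threshold` counts per million for the focal
#' homoeolog in every replicate (`mode = "all"`) or in the pooled replicates
#' (`mode = "pooled"`, CPM of the summed counts over the summed library
#' sizes).
#'
#' @param parent_A_counts raw counts of the A gene across parent-A replicates.
#' @param parent_C_counts raw counts of the C gene across parent-C replicates.
#' @param poly_cpm CPM of the focal homoeolog across the individual's
#'   replicates (for `mode = "pooled"`, supply the pooled CPM as a length-1
#'   value or the per-replicate CPMs, which are then averaged by library
#'   weight only if pre-pooled upstream).
#' @param threshold CPM threshold (default 10, strict `>`).
#' @param mode `"all"` (every replicate, default) or `"pooled"`.
#' @return `TRUE` iff the rule fires.
#' @export
call_novel <- function(parent_A_counts, parent_C_counts, poly_cpm,
                       threshold = 10, mode = c("all", "pooled")) {
  mode <- match.arg(mode)
  parents_zero <- all(parent_A_counts == 0) && all(parent_C_counts == 0)
  expressed <- if (mode == "all") all(poly_cpm > threshold)
               else mean(poly_cpm) > threshold
  parents_zero && expressed
}

#' Silencing rule for one homoeolog
#'
#' A homoeolog is silenced in a polyploid individual iff the corresponding
#' parent expresses it above `threshold` CPM (every replicate for
#' `mode = "all"`, pooled mean for `mode = "pooled"`) while the polyploid has
#' zero raw counts for it in every replicate. Evaluating per subgenome is
#' what enables the SILENCE_AA vs SILENCE_CC comparison.
#'
#' @param parent_cpm CPM of the homoeolog across the corresponding parent's
#'   replicates.
#' @param poly_counts raw counts of the homoeolog across the individual's
#'   replicates.
#' @inheritParams call_novel
#' @return `TRUE` iff the rule fires.
#' @export
call_silenced <- function(parent_cpm, poly_counts, threshold = 10,
                          mode = c("all", "pooled")) {
  mode <- match.arg(mode)
  high <- if (mode == "all") all(parent_cpm > threshold)
          else mean(parent_cpm) > threshold
  high && all(poly_counts == 0)
}

#' Call activation (novel expression) and silencing for one individual
#'
#' Vectorised application of [call_novel()] and [call_silenced()] over all
#' homoeolog pairs. CPM values are computed on the gene-level count matrix.
#' Novel expression requires both parents at zero for the pair and is
#' assigned to the subgenome(s) whose homoeolog passes the polyploid CPM
#' rule; silencing is evaluated per homoeolog against its own parent.
#'
#' @param x a [count_matrix()] (gene level).
#' @param pairs a `pair_table`.
#' @param sheet sample sheet.
#' @param individual polyploid individual.
#' @param threshold CPM threshold (default 10).
#' @param mode replicate aggregation for the CPM conditions: `"all"`
#'   (default) or `"pooled"`.
#' @return Data frame with one row per homoeolog (`pair_id`, `gene_id`,
#'   `subgenome`, `individual`, `status` in `SILENCED`/`NOVEL`/`NEITHER`).
#' @export
silencing_calls <- function(x, pairs, sheet, individual, threshold = 10,
                            mode = c("all", "pooled")) {
  mode <- match.arg(mode)
  m <- as_count_mat(x)
  cpm_m <- cpm(m)
  pa <- group_samples(sheet, "PARENT_A")
  pc <- group_samples(sheet, "PARENT_C")
  poly <- group_samples(sheet, paste0("POLYPLOID/", individual))
  pooled_cpm <- function(counts_mat, cols) {
    rowSums(counts_mat[, cols, drop = FALSE]) * 1e6 /
      sum(colSums(m[, cols, drop = FALSE]))
  }
  above <- function(gene_ids, cols) {
    if (mode == "all") {
      rowSums(cpm_m[gene_ids, cols, drop = FALSE] > threshold) == length(cols)
    } else {
      pooled_cpm(m[gene_ids, , drop = FALSE], cols) > threshold
    }
  }
  zero_in <- function(gene_ids, cols)
    rowSums(m[gene_ids, cols, drop = FALSE]) == 0
  a <- pairs$gene_A; c_ <- pairs$gene_C
  parents_zero <- zero_in(a, pa) & zero_in(c_, pc)
  novel_a <- parents_zero & above(a, poly)
  novel_c <- parents_zero & above(c_, poly)
  sil_a <- above(a, pa) & zero_in(a, poly)
  sil_c <- above(c_, pc) & zero_in(c_, poly)
  status <- function(sil, nov) ifelse(sil, "SILENCED",
                                      ifelse(nov, "NOVEL", "NEITHER"))
  out <- rbind(
    data.frame(pair_id = pairs$pair_id, gene_id = a, subgenome = "A",
               individual = individual, status = status(sil_a, novel_a),
               stringsAsFactors = FALSE),
    data.frame(pair_id = pairs$pair_id, gene_id = c_, subgenome = "C",
               individual = individual, status = status(sil_c, novel_c),
               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Summarise activation/silencing calls across individuals
#'
#' Counts of `NOVEL` and `SILENCED` homoeologs per subgenome and individual,
#' plus totals and a two-proportion chi-square test (no continuity
#' correction) comparing the two subgenomes' total counts against the pair
#' universe.
#'
#' @param calls a data frame of per-individual calls, e.g. `rbind()` of
#'   [silencing_calls()] outputs.
#' @param n_pairs number of homoeolog pairs (the per-subgenome gene universe).
#' @return List with `by_individual` (one row per individual:
#'   `novel_A`, `novel_C`, `silenced_A`, `silenced_C`), `totals`, and
#'   `tests` (chi-square p-values for NOVEL and SILENCED A-vs-C totals).
#' @export
silencing_summary <- function(calls, n_pairs) {
  inds <- sort(unique(calls$individual))
  cnt <- function(ind, st, sg)
    sum(calls$individual == ind & calls$status == st & calls$subgenome == sg)
  by_ind <- data.frame(
    individual = inds,
    novel_A = vapply(inds, cnt, 0L, st = "NOVEL", sg = "A"),
    novel_C = vapply(inds, cnt, 0L, st = "NOVEL", sg = "C"),
    silenced_A = vapply(inds, cnt, 0L, st = "SILENCED", sg = "A"),
    silenced_C = vapply(inds, cnt, 0L, st = "SILENCED", sg = "C"),
    stringsAsFactors = FALSE)
  rownames(by_ind) <- NULL
  totals <- colSums(by_ind[, -1L, drop = FALSE])
  prop_test <- function(na, nc) {
    if (na + nc == 0) return(NA_real_)
    tab <- matrix(c(na, n_pairs * length(inds) - na,
                    nc, n_pairs * length(inds) - nc), nrow = 2L, byrow = TRUE)
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }
  list(by_individual = by_ind,
       totals = totals,
       tests = c(novel = prop_test(totals[["novel_A"]], totals[["novel_C"]]),
                 silenced = prop_test(totals[["silenced_A"]],
                                      totals[["silenced_C"]])))
}
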