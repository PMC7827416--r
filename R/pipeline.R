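#' Run the full allopolyploid expression-pattern analysis
#'
#' Orchestrates every stage for all polyploid individuals: pair-level matrix,
#' median-of-ratios size factors (computed once on the pair-level matrix and
#' reused everywhere), parent-vs-parent DE, and per individual the two
#' parent contrasts, 12-category ELD classification, mid-parent
#' non-additivity, homoeolog-bias transitions and activation/silencing
#' calls; finally the cross-individual combined-pattern set reports and,
#' if trait grades are supplied, the trait dendrogram.
#'
#' @param x a [count_matrix()] or an `allo_sim` object from
#'   [simulate_allopolyploid()] (in which case `sheet` and `pairs` are taken
#'   from it).
#' @param sheet a [as_sample_sheet()] data frame.
#' @param pairs a `pair_table`.
#' @param alpha adjusted-p threshold for every test (default 0.05).
#' @param cpm_threshold CPM threshold of the activation/silencing rules.
#' @param traits optional [as_trait_matrix()] data frame.
#' @param individuals subset of polyploid individuals to analyse (default
#'   all in the sheet).
#' @param verbose print progress messages.
#' @return Object of class `alloexpr_report`; see [summary.alloexpr_report()]
#'   and [write_report()].
#' @export
run_all <- function(x, sheet = NULL, pairs = NULL, alpha = 0.05,
                    cpm_threshold = 10, traits = NULL, individuals = NULL,
                    verbose = FALSE) {
  if (inherits(x, "allo_sim")) {
    sheet <- sheet %||% x$sheet
    pairs <- pairs %||% x$pairs
    x <- x$counts
  }
  if (is.null(sheet) || is.null(pairs))
    stopf("run_all needs a sample sheet and a pair table")
  say <- function(...) if (verbose) message(sprintf(...))
  inds <- individuals %||% poly_individuals(sheet)
  if (length(inds) == 0L) stopf("no polyploid individuals in the sample sheet")

  say("stage pair_matrix: %d pairs x %d samples", nrow(pairs), nrow(sheet))
  pm <- pair_level_matrix(x, pairs, sheet)
  sf <- size_factors(pm)
  say("stage de_parents")
  de_ac <- call_de(pm, sheet, c("PARENT_A", "PARENT_C"), alpha, sf = sf)
  say("stage parental_bias")
  pbias <- parental_bias(x, pairs, sheet, alpha, sf = sf)

  per_ind <- list()
  for (ind in inds) {
    say("individual %s", ind)
    grp <- paste0("POLYPLOID/", ind)
    de_ta <- call_de(pm, sheet, c("PARENT_A", grp), alpha, sf = sf)
    de_tc <- call_de(pm, sheet, c("PARENT_C", grp), alpha, sf = sf)
    eld <- classify_individual(de_ta, de_tc, de_ac, ind)
    nonadd <- test_nonadditive(pm, sheet, ind, sf = sf, alpha = alpha)
    hbias <- hybrid_bias(x, pairs, sheet, ind, alpha, sf = sf)
    trans <- classify_transition(
      pbias$state[match(hbias$pair_id, pbias$pair_id)], hbias$state)
    sil <- silencing_calls(x, pairs, sheet, ind, cpm_threshold)
    per_ind[[ind]] <- list(
      de_TA = de_ta, de_TC = de_tc, eld = eld,
      eld_summary = pattern_summary(eld, nrow(pairs)),
      nonadditive = nonadd,
      hybrid_bias = hbias,
      transitions = data.frame(pair_id = hbias$pair_id, transition = trans,
                               stringsAsFactors = FALSE),
      bias_summary = bias_summary(trans, hbias$state, nrow(pairs)),
      silencing = sil)
  }

  say("stage cross_individual")
  sets <- derive_pattern_sets(lapply(per_ind, `[[`, "eld"))
  set_reports <- lapply(sets, set_report)
  nonadd_sets <- lapply(per_ind, function(pi) {
    r <- pi$nonadditive$result
    r$unit_id[r$nonadditive]
  })
  set_reports$NONADDITIVE <- set_report(nonadd_sets)

  sil_all <- do.call(rbind, lapply(per_ind, `[[`, "silencing"))
  rownames(sil_all) <- NULL

  tc <- if (!is.null(traits)) trait_cluster(traits) else NULL

  structure(list(
    n_pairs = nrow(pairs), individuals = inds, alpha = alpha,
    cpm_threshold = cpm_threshold,
    size_factors = sf, de_parents = de_ac, parental_bias = pbias,
    per_individual = per_ind, set_reports = set_reports,
    silencing_summary = silencing_summary(sil_all, nrow(pairs)),
    trait_cluster = tc), class = "alloexpr_report")
}

#' Per-individual summary table of a report
#'
#' One row per polyploid individual: differentially expressed pairs versus
#' each parent (up/down), non-additive fraction, combined-pattern fractions,
#' parental-condition fraction of the bias transitions, hybrid A/C bias
#' counts, and activation/silencing counts per subgenome.
#'
#' @param object an `alloexpr_report`.
#' @param ... unused.
#' @return A data frame, one row per individual.
#' @export
summary.alloexpr_report <- function(object, ...) {
  rows <- lapply(names(object$per_individual), function(ind) {
    pi <- object$per_individual[[ind]]
    pat <- pi$eld_summary$pattern
    patf <- stats::setNames(pat$fraction, pat$pattern)
    tr <- pi$bias_summary$transitions
    hy <- stats::setNames(pi$bias_summary$hybrid$count,
                          pi$bias_summary$hybrid$state)
    sil <- object$silencing_summary$by_individual
    sil <- sil[sil$individual == ind, ]
    data.frame(
      individual = ind,
      deg_up_vs_A = sum(pi$de_TA$call == "UP_B"),
      deg_down_vs_A = sum(pi$de_TA$call == "UP_A"),
      deg_up_vs_C = sum(pi$de_TC$call == "UP_B"),
      deg_down_vs_C = sum(pi$de_TC$call == "UP_A"),
      nonadditive_frac = pi$nonadditive$fraction,
      additive_frac = patf[["ADDITIVE"]],
      eld_A_frac = patf[["ELD_A"]], eld_C_frac = patf[["ELD_C"]],
      trans_up_frac = patf[["TRANS_UP"]],
      trans_down_frac = patf[["TRANS_DOWN"]],
      parental_condition_frac =
        tr$fraction[tr$pattern == "PARENTAL_CONDITION"],
      hybrid_A_bias = hy[["A_BIAS"]], hybrid_C_bias = hy[["C_BIAS"]],
      novel_A = sil$novel_A, novel_C = sil$novel_C,
      silenced_A = sil$silenced_A, silenced_C = sil$silenced_C,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.alloexpr_report <- function(x, ...) {
  cat(sprintf("alloexpr_report: %d homoeolog pairs, %d individuals, alpha = %g\n",
              x$n_pairs, length(x$individuals), x$alpha))
  cat(sprintf("parents: %d DE pairs (%d up in C, %d up in A)\n",
              sum(x$de_parents$call != "NS"), sum(x$de_parents$call == "UP_B"),
              sum(x$de_parents$call == "UP_A")))
  s <- summary(x)
  num <- vapply(s, is.numeric, TRUE)
  s[num] <- lapply(s[num], function(v) round(v, 3))
  print(s, row.names = FALSE)
  invisible(x)
}

#' Write every table of a report to a directory
#'
#' Writes the parent DE table, the parental bias states, per-individual ELD
#' assignments, non-additivity, bias and silencing tables, the summary table,
#' the set reports and a machine-readable run manifest (parameters and input
#' dimensions). Output is deterministic: re-running [run_all()] under the
#' same inputs yields bit-identical files.
#'
#' @param report an `alloexpr_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_table(as.data.frame(report$de_parents), p("de_parents.tsv"))
  write_table(report$parental_bias, p("parental_bias.tsv"))
  write_table(summary(report), p("summary.tsv"))
  for (ind in names(report$per_individual)) {
    pi <- report$per_individual[[ind]]
    write_table(pi$eld, p(sprintf("eld_%s.tsv", ind)))
    write_table(pi$nonadditive$result, p(sprintf("nonadditive_%s.tsv", ind)))
    b <- merge(pi$hybrid_bias, pi$transitions, by = "pair_id", sort = TRUE)
    write_table(b, p(sprintf("bias_%s.tsv", ind)))
    write_table(pi$silencing, p(sprintf("silencing_%s.tsv", ind)))
  }
  fam <- lapply(names(report$set_reports), function(lbl) {
    r <- report$set_reports[[lbl]]
    cbind(label = lbl, r$per_individual,
          union = r$union_size, intersection = r$intersection_size)
  })
  write_table(do.call(rbind, fam), p("set_report.tsv"))
  manifest <- c(
    sprintf("package=alloexpr %s", as.character(utils::packageVersion("alloexpr"))),
    sprintf("n_pairs=%d", report$n_pairs),
    sprintf("individuals=%s", paste(report$individuals, collapse = ",")),
    sprintf("alpha=%g", report$alpha),
    sprintf("cpm_threshold=%g", report$cpm_threshold),
    sprintf("size_factors=%s",
            paste(sprintf("%s:%.6f", names(report$size_factors),
                          report$size_factors), collapse = ",")))
  writeLines(manifest, p("manifest.txt"))
  invisible(dir)
}
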