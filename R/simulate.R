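default_class_proportions <- c(
  CONSERVED = 0.46, ADDITIVE = 0.13, ELD_A = 0.16, ELD_C = 0.05,
  TRANS_UP = 0.10, TRANS_DOWN = 0.04, NONADDITIVE_ONLY = 0.02,
  SILENCED_A = 0.01, SILENCED_C = 0.02, NOVEL = 0.01)

#' Configuration for the allopolyploid count simulator
#'
#' Defines the study design the simulator emulates: two diploid parents and
#' `n_individuals` allopolyploid plants, each with `replicates` biological
#' replicates; `n_pairs` homoeolog pairs, each planted with one expression
#' class; negative-binomial counts (`variance = mean + dispersion * mean^2`)
#' with log-uniform library-depth variation.
#'
#' @param n_pairs number of homoeolog pairs (default 25000).
#' @param n_individuals number of polyploid individuals (default 8).
#' @param replicates biological replicates per genotype (default 3).
#' @param class_proportions named proportions over the planted classes
#'   `CONSERVED`, `ADDITIVE`, `ELD_A`, `ELD_C`, `TRANS_UP`, `TRANS_DOWN`,
#'   `NONADDITIVE_ONLY`, `SILENCED_A`, `SILENCED_C`, `NOVEL`; must sum to 1.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   baseline expression mean (in expected counts at nominal depth).
#' @param baseline_min floor on the baseline mean, ensuring planted effects
#'   act on clearly expressed genes (default 200).
#' @param effect_log2fc planted effect size in log2 units (default 4).
#' @param dispersion NB dispersion shared by the generator (default 0.05);
#'   0 gives Poisson counts.
#' @param depth_range range of the log-uniform per-sample depth factor
#'   relative to nominal (default `c(0.5, 2)`).
#' @param parental_bias_fraction probability that an orientable planted class
#'   points its parental fold toward the A side (default 0.5).
#' @param bias_preservation probability that a pair's polyploid homoeolog
#'   split preserves the parental ratio; non-preserved pairs fall to a 1:1
#'   split or acquire a new bias (default 0.8).
#' @param cpm_threshold the CPM rule threshold the silenced/novel classes are
#'   planted against; their expressed sides target 5x this CPM and draws are
#'   floored at 2x so the threshold rules recover them exactly.
#' @param seed integer RNG seed.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 25000L, n_individuals = 8L, replicates = 3L,
                       class_proportions = default_class_proportions,
                       baseline_meanlog = log(500), baseline_sdlog = 0.6,
                       baseline_min = 200, effect_log2fc = 4,
                       dispersion = 0.05, depth_range = c(0.5, 2),
                       parental_bias_fraction = 0.5, bias_preservation = 0.8,
                       cpm_threshold = 10, seed = 1L) {
  if (n_pairs < 1 || n_individuals < 1 || replicates < 1)
    stopf("n_pairs, n_individuals and replicates must be positive")
  need <- names(default_class_proportions)
  if (!setequal(names(class_proportions), need))
    stopf("class_proportions must be named over: %s",
          paste(need, collapse = ", "))
  class_proportions <- class_proportions[need]
  if (abs(sum(class_proportions) - 1) > 1e-9 || any(class_proportions < 0))
    stopf("class_proportions must be non-negative and sum to 1")
  if (effect_log2fc < 0 || dispersion < 0)
    stopf("effect_log2fc and dispersion must be >= 0")
  if (baseline_min <= 0 || any(depth_range <= 0) ||
      depth_range[2] < depth_range[1])
    stopf("scale parameters must be positive")
  if (parental_bias_fraction < 0 || parental_bias_fraction > 1 ||
      bias_preservation < 0 || bias_preservation > 1)
    stopf("fractions must lie in [0, 1]")
  structure(list(n_pairs = as.integer(n_pairs),
                 n_individuals = as.integer(n_individuals),
                 replicates = as.integer(replicates),
                 class_proportions = class_proportions,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 baseline_min = baseline_min,
                 effect_log2fc = effect_log2fc,
                 dispersion = dispersion,
                 depth_range = depth_range,
                 parental_bias_fraction = parental_bias_fraction,
                 bias_preservation = bias_preservation,
                 cpm_threshold = cpm_threshold,
                 seed = as.integer(seed)),
            class = "sim_config")
}

with_sim_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

sign_rel <- function(x, y, lo, eq, hi, tol = 1e-9) {
  ifelse(abs(x - y) <= tol * pmax(1, abs(x), abs(y)), eq,
         ifelse(x < y, lo, hi))
}

#' Simulate an allopolyploid expression study with planted truth
#'
#' Draws subgenome-resolved counts for two diploid parents and a set of
#' allopolyploid individuals under the design in [sim_config()], planting a
#' known expression class per homoeolog pair, and records the planting in a
#' truth table so every downstream classification can be scored.
#'
#' Class constructions (baseline mean `m`, effect `e = 2^effect_log2fc`):
#' `CONSERVED` all means equal `m`; `ADDITIVE` parents at `m * 2^(+-eff/2)`
#' with the total at their geometric midpoint `m` (category I/XII);
#' `ELD_A`/`ELD_C` parents differ by `e` with the total pinned to the
#' matching parent; `TRANS_UP`/`TRANS_DOWN` parents equal `m` with the total
#' at `m * e` / `m / e`; `NONADDITIVE_ONLY` parents differ by `e` with the
#' total strictly between them but off the arithmetic mid-parent value;
#' `SILENCED_*` the matching parent is expressed at 5x the CPM threshold
#' while the polyploid copy is a structural zero; `NOVEL` both parents are
#' structural zeros while one polyploid copy is expressed at 5x the
#' threshold. Expressed sides of the threshold classes are floored at 2x the
#' threshold so the rules recover them deterministically.
#'
#' @param config a [sim_config()].
#' @return List of class `allo_sim` with `counts` ([count_matrix()]),
#'   `sheet`, `pairs`, `truth` (data frame: `pair_id`, `class`,
#'   `roman_expected`, `pattern_expected`, `nonadditive` (NA for threshold
#'   classes), `parent_bias`, `hybrid_bias`, `silenced_A`, `silenced_C`,
#'   `novel_A`, `novel_C`), and `depths`.
#' @export
simulate_allopolyploid <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed, {
    n <- config$n_pairs
    reps <- config$replicates
    eff <- config$effect_log2fc
    e <- 2^eff; half <- 2^(eff / 2); quarter <- 2^(eff / 4)
    cls <- sample(names(config$class_proportions), n, replace = TRUE,
                  prob = config$class_proportions)
    m <- pmax(config$baseline_min,
              stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog))
    ahigh <- stats::runif(n) < config$parental_bias_fraction

    pA <- m; pC <- m; Tt <- m
    idx <- cls == "ADDITIVE"
    pA[idx] <- ifelse(ahigh[idx], m[idx] * half, m[idx] / half)
    pC[idx] <- ifelse(ahigh[idx], m[idx] / half, m[idx] * half)
    idx <- cls == "ELD_A"
    pA[idx] <- ifelse(ahigh[idx], m[idx] * e, m[idx])
    pC[idx] <- ifelse(ahigh[idx], m[idx], m[idx] * e)
    Tt[idx] <- pA[idx]
    idx <- cls == "ELD_C"
    pA[idx] <- ifelse(ahigh[idx], m[idx] * e, m[idx])
    pC[idx] <- ifelse(ahigh[idx], m[idx], m[idx] * e)
    Tt[idx] <- pC[idx]
    idx <- cls == "TRANS_UP";   Tt[idx] <- m[idx] * e
    idx <- cls == "TRANS_DOWN"; Tt[idx] <- m[idx] / e
    idx <- cls == "NONADDITIVE_ONLY"
    pA[idx] <- ifelse(ahigh[idx], m[idx] * e, m[idx])
    pC[idx] <- ifelse(ahigh[idx], m[idx], m[idx] * e)
    Tt[idx] <- m[idx] * quarter

    # threshold classes: expressed sides target high_cpm; solve for the mean
    # that yields that CPM given it contributes to the column total itself
    thr <- config$cpm_threshold
    high_cpm <- 5 * thr
    is_sa <- cls == "SILENCED_A"; is_sc <- cls == "SILENCED_C"
    is_nov <- cls == "NOVEL"
    pA[is_nov] <- 0; pC[is_nov] <- 0
    novel_focal_A <- is_nov & (cumsum(is_nov) %% 2L == 1L)  # alternate A/C
    cfrac <- high_cpm / 1e6
    xa <- cfrac * sum(pA[!is_sa]) / (1 - cfrac * sum(is_sa))
    pA[is_sa] <- xa
    xc <- cfrac * sum(pC[!is_sc]) / (1 - cfrac * sum(is_sc))
    pC[is_sc] <- xc

    # polyploid homoeolog split
    hA <- numeric(n); hC <- numeric(n)
    ordinary <- !(is_sa | is_sc | is_nov)
    r <- ifelse(pC > 0, pA / pC, Inf)
    preserved <- stats::runif(n) < config$bias_preservation
    to_equal <- stats::runif(n) < 0.5      # non-preserved: lose vs gain bias
    gain_dir_A <- stats::runif(n) < 0.5
    frac_A <- ifelse(preserved, r / (1 + r),
                     ifelse(to_equal, 0.5,
                            ifelse(gain_dir_A, e / (1 + e), 1 / (1 + e))))
    hA[ordinary] <- Tt[ordinary] * frac_A[ordinary]
    hC[ordinary] <- Tt[ordinary] * (1 - frac_A[ordinary])
    hA[is_sa] <- 0;            hC[is_sa] <- Tt[is_sa] <- m[is_sa]
    hC[is_sc] <- 0;            hA[is_sc] <- Tt[is_sc] <- m[is_sc]
    # novel focal copy targets high_cpm of the polyploid column total
    S0_poly <- sum(Tt[!is_nov])
    xp <- cfrac * S0_poly / (1 - cfrac * sum(is_nov))
    Tt[is_nov] <- xp
    hA[is_nov] <- ifelse(novel_focal_A[is_nov], xp, 0)
    hC[is_nov] <- ifelse(novel_focal_A[is_nov], 0, xp)

    # truth table
    d_ac <- sign_rel(pA, pC, "A<C", "A=C", "A>C")
    d_ta <- sign_rel(Tt, pA, "T<A", "T=A", "T>A")
    d_tc <- sign_rel(Tt, pC, "T<C", "T=C", "T>C")
    roman_exp <- classify_triple(d_ac, d_ta, d_tc)
    mpv_true <- (pA + pC) / 2
    nonadd <- ifelse(is_sa | is_sc | is_nov, NA,
                     abs(Tt - mpv_true) > 1e-6 * pmax(1, mpv_true))
    parent_bias <- sign_rel(pC, pA, "C_BIAS", "NO_BIAS", "A_BIAS")
    hybrid_bias <- sign_rel(hC, hA, "C_BIAS", "NO_BIAS", "A_BIAS")

    pair_id <- sprintf("HP%06d", seq_len(n))
    gene_A <- sprintf("A%06d", seq_len(n))
    gene_C <- sprintf("C%06d", seq_len(n))
    truth <- data.frame(pair_id = pair_id, class = cls,
                        roman_expected = roman_exp,
                        pattern_expected = eld_pattern(roman_exp),
                        nonadditive = nonadd,
                        parent_bias = parent_bias, hybrid_bias = hybrid_bias,
                        silenced_A = is_sa, silenced_C = is_sc,
                        novel_A = novel_focal_A,
                        novel_C = is_nov & !novel_focal_A,
                        stringsAsFactors = FALSE)

    inds <- sprintf("AACC%d", seq_len(config$n_individuals))
    sheet <- data.frame(
      sample_id = c(paste0("PA_", seq_len(reps)), paste0("PC_", seq_len(reps)),
                    unlist(lapply(inds, function(i) paste0(i, "_", seq_len(reps))))),
      genotype = c(rep("PARENT_A", reps), rep("PARENT_C", reps),
                   rep("POLYPLOID", reps * length(inds))),
      individual = c(rep("", 2 * reps), rep(inds, each = reps)),
      replicate = c(seq_len(reps), seq_len(reps),
                    rep(seq_len(reps), length(inds))),
      stringsAsFactors = FALSE)
    sheet <- as_sample_sheet(sheet)
    n_samp <- nrow(sheet)
    depths <- exp(stats::runif(n_samp, log(config$depth_range[1]),
                               log(config$depth_range[2])))
    names(depths) <- sheet$sample_id

    # expected count means per gene x sample
    mu <- matrix(0, 2L * n, n_samp,
                 dimnames = list(c(gene_A, gene_C), sheet$sample_id))
    geno <- sheet$genotype
    mu[seq_len(n), geno == "PARENT_A"] <- outer(pA, depths[geno == "PARENT_A"])
    mu[n + seq_len(n), geno == "PARENT_C"] <- outer(pC, depths[geno == "PARENT_C"])
    mu[seq_len(n), geno == "POLYPLOID"] <- outer(hA, depths[geno == "POLYPLOID"])
    mu[n + seq_len(n), geno == "POLYPLOID"] <- outer(hC, depths[geno == "POLYPLOID"])

    counts <- matrix(0L, nrow(mu), ncol(mu), dimnames = dimnames(mu))
    pos <- mu > 0
    if (config$dispersion > 0) {
      counts[pos] <- stats::rnbinom(sum(pos), mu = mu[pos],
                                    size = 1 / config$dispersion)
    } else {
      counts[pos] <- stats::rpois(sum(pos), mu[pos])
    }

    # floor the expressed sides of the threshold classes at 2x the CPM rule
    floor_at <- function(rows, cols, col_totals) {
      fl <- outer(rep(1, length(rows)), ceiling(2 * thr * 1e-6 * col_totals))
      counts[rows, cols] <<- pmax(counts[rows, cols, drop = FALSE], fl)
    }
    exp_tot <- colSums(mu)
    pa_cols <- sheet$sample_id[geno == "PARENT_A"]
    pc_cols <- sheet$sample_id[geno == "PARENT_C"]
    po_cols <- sheet$sample_id[geno == "POLYPLOID"]
    if (any(is_sa)) floor_at(which(is_sa), pa_cols, exp_tot[pa_cols])
    if (any(is_sc)) floor_at(n + which(is_sc), pc_cols, exp_tot[pc_cols])
    if (any(novel_focal_A))
      floor_at(which(novel_focal_A), po_cols, exp_tot[po_cols])
    if (any(is_nov & !novel_focal_A))
      floor_at(n + which(is_nov & !novel_focal_A), po_cols, exp_tot[po_cols])

    cm <- count_matrix(counts,
                       stats::setNames(rep(c("A", "C"), each = n),
                                       c(gene_A, gene_C)))
    pairs <- as_pair_table(data.frame(
      pair_id = pair_id, gene_A = gene_A, gene_C = gene_C,
      identity_pct = round(stats::runif(n, 90.5, 99.5), 1),
      evalue = 10^-stats::runif(n, 12, 60), stringsAsFactors = FALSE))
    structure(list(counts = cm, sheet = sheet, pairs = pairs, truth = truth,
                   depths = depths, config = config),
              class = "allo_sim")
  })
}

#' @export
print.allo_sim <- function(x, ...) {
  cat(sprintf("allo_sim: %d pairs, %d individuals x %d replicates (seed %d)\n",
              x$config$n_pairs, x$config$n_individuals, x$config$replicates,
              x$config$seed))
  print(round(prop.table(table(x$truth$class)), 3))
  invisible(x)
}

#' Score classified results against the planted truth
#'
#' Given the truth table of [simulate_allopolyploid()] and either a single
#' `category_assignment` data frame or a full [run_all()] report, computes an
#' exact confusion matrix of planted versus recovered expression pattern and
#' per-class recall/precision; with a full report it additionally scores
#' non-additive detection, the CONSERVED false-positive rate and the
#' silencing/novel calls.
#'
#' @param truth truth table data frame.
#' @param results a `category_assignment` data frame or an `alloexpr_report`.
#' @return List with `confusion`, `per_class` (recall/precision per planted
#'   pattern) and, for a report, `conserved_fpr`, `nonadditive_recall`,
#'   `silenced_recall`, `novel_recall`.
#' @export
evaluate_recovery <- function(truth, results) {
  patterns <- c("CONSERVED", "ADDITIVE", "ELD_A", "ELD_C", "TRANS_UP",
                "TRANS_DOWN", "AMBIGUOUS")
  score_assign <- function(assign) {
    if (nrow(assign) > 0 && !all(assign$pair_id %in% truth$pair_id))
      stopf("assignment contains pair ids absent from the truth table")
    planted <- truth$pattern_expected[match(assign$pair_id, truth$pair_id)]
    conf <- table(planted = factor(planted, levels = patterns),
                  recovered = factor(assign$pattern, levels = patterns))
    n_planted <- table(factor(truth$pattern_expected, levels = patterns))
    # recall denominators count every planted pair (per individual pass)
    list(conf = conf, n_planted = n_planted)
  }
  finish <- function(conf, planted_totals) {
    diagv <- diag(conf)
    recall <- ifelse(planted_totals > 0, diagv / planted_totals, 0)
    colsum <- colSums(conf)
    precision <- ifelse(colsum > 0, diagv / colsum, 0)
    list(confusion = conf,
         per_class = data.frame(pattern = patterns,
                                planted = as.integer(planted_totals),
                                recovered = as.integer(diagv),
                                recall = as.numeric(recall),
                                precision = as.numeric(precision),
                                stringsAsFactors = FALSE))
  }
  if (inherits(results, "alloexpr_report")) {
    assigns <- lapply(results$per_individual, `[[`, "eld")
    conf <- NULL; tot <- NULL
    for (a in assigns) {
      s <- score_assign(a)
      conf <- if (is.null(conf)) s$conf else conf + s$conf
      tot <- if (is.null(tot)) s$n_planted else tot + s$n_planted
    }
    out <- finish(conf, tot)
    cons <- truth$pair_id[truth$pattern_expected == "CONSERVED"]
    fp <- vapply(assigns, function(a) {
      sub <- a[a$pair_id %in% cons, ]
      mean(sub$pattern != "CONSERVED")
    }, 0)
    out$conserved_fpr <- mean(fp)
    na_true <- truth$pair_id[!is.na(truth$nonadditive) & truth$nonadditive]
    rec <- vapply(results$per_individual, function(pi) {
      r <- pi$nonadditive$result
      mean(r$nonadditive[r$unit_id %in% na_true])
    }, 0)
    out$nonadditive_recall <- mean(rec)
    sil_rec <- function(flag_col, sg) {
      ids <- truth$pair_id[truth[[flag_col]]]
      if (length(ids) == 0L) return(NA_real_)
      mean(vapply(results$per_individual, function(pi) {
        s <- pi$silencing
        mean(s$status[s$pair_id %in% ids & s$subgenome == sg] ==
               if (grepl("silenced", flag_col)) "SILENCED" else "NOVEL")
      }, 0))
    }
    out$silenced_recall <- mean(c(sil_rec("silenced_A", "A"),
                                  sil_rec("silenced_C", "C")), na.rm = TRUE)
    out$novel_recall <- mean(c(sil_rec("novel_A", "A"),
                               sil_rec("novel_C", "C")), na.rm = TRUE)
    return(out)
  }
  s <- score_assign(results)
  finish(s$conf, s$n_planted)
}
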