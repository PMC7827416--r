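#' Derive combined-pattern gene-set families across individuals
#'
#' From per-individual 12-category assignments, builds the six combined sets
#' per individual: `BIA_A = IV + IX` (total biased to the A parent's level),
#' `BIA_C = II + XI`, `HIGH_PARENTS = II + IV` (dominance toward the higher
#' parent), `DOWN_PARENTS = IX + XI`, `TRANS_UP = V + VI + VIII`,
#' `TRANS_DOWN = III + VII + X`.
#'
#' @param assignments named list (one element per individual) of
#'   `category_assignment` data frames from [classify_individual()].
#' @return Named list of families; each family is a named list mapping an
#'   individual to its character vector of pair ids.
#' @export
derive_pattern_sets <- function(assignments) {
  defs <- list(BIA_A = c("IV", "IX"), BIA_C = c("II", "XI"),
               HIGH_PARENTS = c("II", "IV"), DOWN_PARENTS = c("IX", "XI"),
               TRANS_UP = c("V", "VI", "VIII"),
               TRANS_DOWN = c("III", "VII", "X"))
  known <- c(as.character(as.roman(1:12)), "CONSERVED", "AMBIGUOUS")
  for (a in assignments) {
    bad <- setdiff(unique(a$roman), known)
    if (length(bad)) stopf("unknown roman label '%s'", bad[1L])
  }
  lapply(defs, function(romans) {
    lapply(assignments, function(a) a$pair_id[a$roman %in% romans])
  })
}

#' Set-algebra report for one gene-set family
#'
#' For a family of per-individual gene-id sets, reports each individual's set
#' size and specific count (members found in no other individual), all
#' pairwise intersection sizes, the union and the global intersection.
#'
#' @param family named list mapping individuals to character vectors of ids.
#' @return List with `per_individual` (data frame `individual`, `size`,
#'   `specific`), `pairwise` (matrix of intersection sizes), `union_size`,
#'   `intersection_size`, `union`, `intersection`.
#' @export
set_report <- function(family) {
  if (length(family) < 1L) stopf("set report needs >= 1 individual")
  family <- lapply(family, unique)
  inds <- names(family) %||% as.character(seq_along(family))
  names(family) <- inds
  all_union <- sort(unique(unlist(family, use.names = FALSE)))
  global_int <- all_union
  for (s in family) global_int <- intersect(global_int, s)
  specific <- vapply(seq_along(family), function(i) {
    others <- unique(unlist(family[-i], use.names = FALSE))
    sum(!(family[[i]] %in% others))
  }, 0L)
  pw <- outer(seq_along(family), seq_along(family),
              Vectorize(function(i, j) length(intersect(family[[i]], family[[j]]))))
  dimnames(pw) <- list(inds, inds)
  list(per_individual = data.frame(individual = inds,
                                   size = lengths(family),
                                   specific = specific,
                                   stringsAsFactors = FALSE,
                                   row.names = NULL),
       pairwise = pw,
       union_size = length(all_union),
       intersection_size = length(global_int),
       union = all_union,
       intersection = sort(global_int))
}

#' Hierarchically cluster individuals by trait grades
#'
#' Grades are standardised per trait (zero mean, unit variance; constant
#' traits are dropped), individuals are compared by Euclidean distance and
#' clustered with average linkage. Rows are sorted by individual label before
#' clustering so the result does not depend on input order.
#'
#' @param traits a [as_trait_matrix()] data frame.
#' @return List of class `trait_clust` with `hclust` (the [stats::hclust()]
#'   object), `merge`, `heights` and `order` (leaf labels left to right).
#' @export
trait_cluster <- function(traits) {
  traits <- as_trait_matrix(traits)
  if (nrow(traits) < 2L) stopf("clustering needs >= 2 individuals")
  traits <- traits[order(traits$individual), , drop = FALSE]
  g <- as.matrix(traits[setdiff(names(traits), "individual")])
  rownames(g) <- traits$individual
  keep <- apply(g, 2L, function(v) stats::sd(v) > 0)
  if (!any(keep)) stopf("all traits are constant; no clustering signal")
  z <- scale(g[, keep, drop = FALSE])
  h <- stats::hclust(stats::dist(z, method = "euclidean"), method = "average")
  structure(list(hclust = h, merge = h$merge, heights = h$height,
                 order = h$labels[h$order]),
            class = "trait_clust")
}

#' @export
print.trait_clust <- function(x, ...) {
  cat("trait_clust:", length(x$order), "individuals\n")
  cat("leaf order:", paste(x$order, collapse = " "), "\n")
  cat("merge heights:", paste(signif(x$heights, 4), collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.trait_clust <- function(x, ...) plot(x$hclust, ...)
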