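#' Parse BLAST tabular output (12-column outfmt-6 dialect)
#'
#' Reads gene-model-vs-gene-model hits of A-subgenome queries against
#' C-subgenome subjects. Only the columns used downstream are retained:
#' query, subject, percent identity, alignment length, E-value and bit score.
#'
#' @param path path to a tab-separated 12-column BLAST hit file (no header;
#'   `#` comment lines are ignored).
#' @return A data frame of hits with columns `query`, `subject`,
#'   `identity_pct`, `align_len`, `evalue`, `bitscore`.
#' @seealso [filter_hits()], [build_pairs()]
#' @export
parse_blast_tab <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  empty <- data.frame(query = character(), subject = character(),
                      identity_pct = numeric(), align_len = integer(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L))
    stopf("format error: line %d has %d columns (expected 12)",
          which(nf != 12L)[1L], nf[nf != 12L][1L])
  m <- do.call(rbind, parts)
  hits <- data.frame(query = m[, 1L], subject = m[, 2L],
                     identity_pct = as.numeric(m[, 3L]),
                     align_len = as.integer(m[, 4L]),
                     evalue = as.numeric(m[, 11L]),
                     bitscore = as.numeric(m[, 12L]),
                     stringsAsFactors = FALSE)
  if (any(is.na(hits$identity_pct)) || any(is.na(hits$evalue)) ||
      any(is.na(hits$bitscore)))
    stopf("format error: non-numeric identity, evalue or bitscore field")
  if (any(hits$identity_pct < 0 | hits$identity_pct > 100) ||
      any(hits$evalue < 0))
    stopf("format error: identity must be in [0,100] and evalue >= 0")
  hits
}

#' Filter BLAST hits by homology thresholds
#'
#' Retains exactly the hits with E-value at most `max_evalue` (cutoff read
#' inclusively) and percent identity strictly greater than `min_identity`.
#'
#' @param hits data frame from [parse_blast_tab()].
#' @param max_evalue inclusive E-value cutoff (default `1e-10`).
#' @param min_identity exclusive identity threshold in percent (default `90`).
#' @return The retained subset of `hits`.
#' @export
filter_hits <- function(hits, max_evalue = 1e-10, min_identity = 90) {
  hits[hits$evalue <= max_evalue & hits$identity_pct > min_identity, ,
       drop = FALSE]
}

#' Build a one-to-one homoeolog pair table from filtered hits
#'
#' Greedy best-hit matching: all hits are ranked by bit score (descending),
#' then E-value (ascending), then subject and query id (lexicographic, so the
#' result is deterministic); the ranked list is swept and a hit is kept iff
#' neither endpoint has been paired yet. Equivalent to brute-force greedy
#' maximum-score matching under that ordering.
#'
#' @param hits data frame of already-filtered hits (see [filter_hits()]).
#' @return A `pair_table` data frame (see [as_pair_table()]); empty input
#'   yields an empty table.
#' @export
build_pairs <- function(hits) {
  if (nrow(hits) == 0L) {
    return(as_pair_table(data.frame(pair_id = character(),
                                    gene_A = character(), gene_C = character(),
                                    identity_pct = numeric(), evalue = numeric(),
                                    stringsAsFactors = FALSE)))
  }
  ord <- order(-hits$bitscore, hits$evalue, hits$subject, hits$query)
  hits <- hits[ord, , drop = FALSE]
  used_a <- character(); used_c <- character()
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!(hits$query[i] %in% used_a) && !(hits$subject[i] %in% used_c)) {
      keep[i] <- TRUE
      used_a <- c(used_a, hits$query[i])
      used_c <- c(used_c, hits$subject[i])
    }
  }
  kept <- hits[keep, , drop = FALSE]
  kept <- kept[order(kept$query), , drop = FALSE]
  as_pair_table(data.frame(pair_id = sprintf("HP%06d", seq_len(nrow(kept))),
                           gene_A = kept$query, gene_C = kept$subject,
                           identity_pct = kept$identity_pct,
                           evalue = kept$evalue,
                           stringsAsFactors = FALSE))
}
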