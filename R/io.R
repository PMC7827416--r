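#' Construct a subgenome-tagged count matrix
#'
#' The universal input container of the package: an integer gene-by-sample
#' count matrix in which every gene carries exactly one subgenome label
#' (`"A"` for the maternal-type subgenome, `"C"` for the paternal-type one).
#' Counts are raw (un-normalised) read counts.
#'
#' @param counts integer matrix, genes in rows and samples in columns, with
#'   unique rownames (gene ids) and colnames (sample ids).
#' @param subgenome character vector of `"A"`/`"C"` labels, one per gene,
#'   in row order (or named by gene id).
#' @param gene_lengths optional positive integer vector of gene lengths in
#'   base pairs (row order or named); required only for [fpkm()].
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `subgenome` (named) and `gene_lengths` (named or `NULL`).
#' @seealso [read_counts()], [cpm()], [fpkm()], [pair_level_matrix()]
#' @export
count_matrix <- function(counts, subgenome, gene_lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stopf("format error: duplicate gene id '%s'",
          rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stopf("format error: duplicate sample id")
  if (any(is.na(counts)) || !all(is_wholenumber(counts)) || any(counts < 0))
    stopf("counts must be non-negative integers with no missing cells")
  storage.mode(counts) <- "integer"
  if (!is.null(names(subgenome))) subgenome <- subgenome[rownames(counts)]
  if (length(subgenome) != nrow(counts) || any(is.na(subgenome)))
    stopf("subgenome labels must cover every gene")
  if (!all(subgenome %in% c("A", "C")))
    stopf("subgenome labels must be 'A' or 'C'")
  names(subgenome) <- rownames(counts)
  if (!is.null(gene_lengths)) {
    if (!is.null(names(gene_lengths))) gene_lengths <- gene_lengths[rownames(counts)]
    if (length(gene_lengths) != nrow(counts) || any(is.na(gene_lengths)) ||
        !all(is_wholenumber(gene_lengths)) || any(gene_lengths <= 0))
      stopf("gene_lengths must be positive integers, one per gene")
    gene_lengths <- as.integer(round(gene_lengths))
    names(gene_lengths) <- rownames(counts)
  }
  structure(list(counts = counts, subgenome = subgenome,
                 gene_lengths = gene_lengths),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes (A: %d, C: %d) x %d samples%s\n",
              nrow(x$counts), sum(x$subgenome == "A"), sum(x$subgenome == "C"),
              ncol(x$counts),
              if (is.null(x$gene_lengths)) "" else ", with gene lengths"))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Validate a sample sheet
#'
#' A sample sheet maps sample ids to experimental units: `genotype` is one of
#' `PARENT_A`, `PARENT_C`, `POLYPLOID`; `individual` names the allopolyploid
#' plant (empty for parents); `replicate` is a positive integer. Each
#' genotype/individual present must have at least two biological replicates.
#'
#' @param df data frame with columns `sample_id`, `genotype`, `individual`,
#'   `replicate`.
#' @return The validated data frame (invisibly classed `sample_sheet`).
#' @export
as_sample_sheet <- function(df) {
  need <- c("sample_id", "genotype", "individual", "replicate")
  if (!all(need %in% names(df)))
    stopf("sample sheet must have columns: %s", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$sample_id <- as.character(df$sample_id)
  df$genotype <- as.character(df$genotype)
  df$individual <- as.character(df$individual)
  df$individual[is.na(df$individual)] <- ""
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample_id in sample sheet")
  if (!all(df$genotype %in% c("PARENT_A", "PARENT_C", "POLYPLOID")))
    stopf("genotype must be PARENT_A, PARENT_C or POLYPLOID")
  if (any(df$genotype == "POLYPLOID" & df$individual == ""))
    stopf("POLYPLOID samples must name an individual")
  if (any(is.na(df$replicate)) || !all(is_wholenumber(df$replicate)) ||
      any(df$replicate < 1))
    stopf("replicate must be a positive integer")
  df$replicate <- as.integer(df$replicate)
  key <- paste(df$genotype, df$individual, df$replicate)
  if (anyDuplicated(key))
    stopf("(genotype, individual, replicate) triples must be unique")
  n_rep <- table(paste(df$genotype, df$individual))
  if (any(n_rep < 2L))
    stopf("every genotype/individual needs >= 2 replicates (found %s with %d)",
          names(n_rep)[which.min(n_rep)], min(n_rep))
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read a sample sheet TSV
#' @param path path to a tab-separated file with columns `sample_id`,
#'   `genotype`, `individual`, `replicate`.
#' @return A validated `sample_sheet` data frame.
#' @export
read_sample_sheet <- function(path) as_sample_sheet(read_tsv_file(path))

# Group labels of the form "PARENT_A", "PARENT_C" or "POLYPLOID/AACC3".
group_label <- function(sheet) {
  ifelse(sheet$genotype == "POLYPLOID",
         paste0("POLYPLOID/", sheet$individual), sheet$genotype)
}

# Sample ids belonging to one group label, ordered by replicate index.
group_samples <- function(sheet, group) {
  sel <- sheet[group_label(sheet) == group, , drop = FALSE]
  if (nrow(sel) == 0L) stopf("configuration error: no samples for group '%s'", group)
  sel$sample_id[order(sel$replicate)]
}

poly_individuals <- function(sheet) {
  sort(unique(sheet$individual[sheet$genotype == "POLYPLOID"]))
}

#' Read a counts TSV into a count matrix
#'
#' The expected layout is: a header row, first column `gene_id`, second column
#' `subgenome` (`A`/`C`), an optional `length` column (gene length in bp), then
#' one column per sample. Lines starting with `#` are ignored.
#'
#' @param path path to the counts TSV.
#' @param sample_sheet a validated [as_sample_sheet()] data frame; every sample
#'   column in the file must be listed in the sheet and vice versa.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, sample_sheet) {
  df <- read_tsv_file(path)
  if (!all(c("gene_id", "subgenome") %in% names(df)))
    stopf("format error: counts file needs 'gene_id' and 'subgenome' columns")
  lens <- NULL
  if ("length" %in% names(df)) {
    lens <- df$length
    df$length <- NULL
  }
  sample_cols <- setdiff(names(df), c("gene_id", "subgenome"))
  missing <- setdiff(sample_cols, sample_sheet$sample_id)
  if (length(missing))
    stopf("configuration error: sample '%s' not in sample sheet", missing[1L])
  absent <- setdiff(sample_sheet$sample_id, sample_cols)
  if (length(absent))
    stopf("configuration error: sheet sample '%s' missing from counts file",
          absent[1L])
  if (anyDuplicated(df$gene_id))
    stopf("format error: duplicate gene id '%s'",
          df$gene_id[duplicated(df$gene_id)][1L])
  m <- as.matrix(df[sample_cols])
  if (!is.numeric(m) || any(is.na(m)) || !all(is_wholenumber(m)) || any(m < 0))
    stopf("counts must be non-negative integers")
  rownames(m) <- df$gene_id
  if (!is.null(lens)) names(lens) <- df$gene_id
  count_matrix(m, stats::setNames(as.character(df$subgenome), df$gene_id), lens)
}

#' Write a result table or count matrix as TSV
#'
#' Writing then reading back preserves every cell bit-exactly; an empty result
#' set yields a header-only file.
#'
#' @param x a data frame or a [count_matrix()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_table <- function(x, path) UseMethod("write_table")

#' @export
write_table.data.frame <- function(x, path) write_tsv_file(x, path)

#' @export
write_table.count_matrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x$counts),
                   subgenome = unname(x$subgenome),
                   stringsAsFactors = FALSE)
  if (!is.null(x$gene_lengths)) df$length <- unname(x$gene_lengths)
  df <- cbind(df, as.data.frame(x$counts, optional = TRUE))
  write_tsv_file(df, path)
}

#' Validate a homoeolog pair table
#'
#' Pairs link one A-subgenome gene to one C-subgenome gene (a one-to-one
#' matching) together with the alignment statistics that justified the pair.
#' Retained pairs must satisfy the alignment thresholds: identity strictly
#' above `min_identity` percent and E-value at most `max_evalue`.
#'
#' @param df data frame with columns `pair_id`, `gene_A`, `gene_C`,
#'   `identity_pct`, `evalue`.
#' @param min_identity,max_evalue thresholds every retained pair must satisfy.
#' @return The validated data frame, classed `pair_table`.
#' @export
as_pair_table <- function(df, min_identity = 90, max_evalue = 1e-10) {
  need <- c("pair_id", "gene_A", "gene_C", "identity_pct", "evalue")
  if (!all(need %in% names(df)))
    stopf("pair table must have columns: %s", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  for (col in c("pair_id", "gene_A", "gene_C")) df[[col]] <- as.character(df[[col]])
  if (anyDuplicated(df$pair_id)) stopf("duplicate pair_id")
  if (anyDuplicated(df$gene_A) || anyDuplicated(df$gene_C))
    stopf("pair table must be one-to-one: a gene may appear in at most one pair")
  if (any(df$identity_pct <= min_identity))
    stopf("pair with identity_pct <= %g retained", min_identity)
  if (any(df$evalue > max_evalue))
    stopf("pair with evalue > %g retained", max_evalue)
  class(df) <- c("pair_table", "data.frame")
  df
}

#' Read a homoeolog pair table TSV
#' @inheritParams as_pair_table
#' @param path path to the TSV.
#' @return A validated `pair_table` data frame.
#' @export
read_pairs <- function(path, min_identity = 90, max_evalue = 1e-10) {
  as_pair_table(read_tsv_file(path), min_identity, max_evalue)
}

#' Validate a trait grade matrix
#'
#' One row per allopolyploid individual; every other column is an ordinal
#' trait grade (small integers, e.g. 1-5 scored in the field). No missing
#' cells are allowed.
#'
#' @param df data frame with an `individual` column plus one integer column
#'   per trait.
#' @return The validated data frame, classed `trait_matrix`.
#' @export
as_trait_matrix <- function(df) {
  if (!"individual" %in% names(df)) stopf("trait table needs an 'individual' column")
  df <- as.data.frame(df)
  df$individual <- as.character(df$individual)
  if (anyDuplicated(df$individual)) stopf("duplicate individual in trait table")
  traits <- setdiff(names(df), "individual")
  if (length(traits) == 0L) stopf("trait table has no trait columns")
  for (tr in traits) {
    v <- df[[tr]]
    if (any(is.na(v)) || !all(is_wholenumber(v)))
      stopf("trait '%s' must be integer grades with no missing cells", tr)
    df[[tr]] <- as.integer(round(v))
  }
  class(df) <- c("trait_matrix", "data.frame")
  df
}

#' Read a trait grade TSV
#' @param path path to a TSV with `individual` plus one column per trait.
#' @return A validated `trait_matrix` data frame.
#' @export
read_traits <- function(path) as_trait_matrix(read_tsv_file(path))
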