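# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Round-half-up (0.5 always rounds away from zero for non-negative input);
# base round() is round-half-even and would bias mid-parent pseudo-counts.
round_half_up <- function(x) floor(x + 0.5)

row_var <- function(x) {
  # sample variance per row; NA-free input assumed
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1L)
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

read_tsv_file <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

write_tsv_file <- function(df, path) {
  ok <- try(utils::write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE),
            silent = TRUE)
  if (inherits(ok, "try-error")) stopf("cannot write to '%s'", path)
  invisible(path)
}
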