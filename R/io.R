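# Plain-text table I/O. All outputs are TSV with optional "# key: value"
# header comments (seed provenance); readers skip comment lines.

#' Write a data frame as TSV with optional header comments
#'
#' @param x data.frame.
#' @param path output path.
#' @param comments character vector written as `# ...` lines before the header.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write an ASV-by-sample count matrix as TSV
#'
#' First column `asv_id`, remaining columns one per sample.
#'
#' @param counts integer matrix with ASV row names and sample column names.
#' @inheritParams write_tsv
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, comments = character()) {
  df <- data.frame(asv_id = rownames(counts), counts,
                   check.names = FALSE, row.names = NULL)
  write_tsv(df, path, comments)
}

#' Read an ASV-by-sample count matrix from TSV
#'
#' @param path input path.
#' @return integer matrix with ASV row names.
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

# seed-derivation helper: one user seed fans out to per-stage streams.
# Offsets are fixed per stage so stages are reproducible in isolation.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 7919 * offset) %% .Machine$integer.max)
}
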