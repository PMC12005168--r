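# TSV readers/writers for the pipeline's on-disk formats. All tables are
# plain tab-separated text; the count matrix carries gene_id as its first
# column.

#' Write a count matrix as TSV
#' @param counts Integer matrix genes x samples.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), as.data.frame(counts),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix from TSV
#' @param path File written by [write_count_matrix()].
#' @return Integer matrix with gene row names and sample column names.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write a sample table as TSV
#' @param samples Sample table from [make_design()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample table from TSV
#'
#' Restores `sampling_point` as an ordered factor (by day) and recomputes
#' nothing: the file is taken as authoritative.
#'
#' @param path File written by [write_sample_table()].
#' @return data.frame sample table.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lev <- unique(df$sampling_point[order(df$day)])
  df$sampling_point <- factor(df$sampling_point, levels = lev)
  df
}

#' Write any result data.frame as TSV
#' @param x data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
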