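#' Plain-text I/O helpers
#'
#' TSV readers/writers for the pipeline's tables and a minimal FASTA
#' writer/reader for library sequences (one record per construct).
#'
#' @name io
NULL

#' Write a data.frame as TSV
#' @param x data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a TSV into a data.frame
#' @param path Input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write named sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  out <- character(2 * length(seqs))
  out[c(TRUE, FALSE)] <- paste0(">", names(seqs))
  out[c(FALSE, TRUE)] <- unname(seqs)
  writeLines(out, path)
}

#' Read a FASTA file into a named character vector
#' @param path Input path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  id <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], id[!hdr]), paste, character(1), collapse = "")
  stats::setNames(unname(seqs), sub("^>\\s*", "", lines[hdr]))
}

#' Write a count matrix as TSV (constructs in rows)
#' @param m Matrix with row names.
#' @param path Output path.
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(construct_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a count matrix written by [write_count_matrix()]
#' @param path Input path.
#' @return Numeric matrix with construct_id row names.
#' @export
read_count_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
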