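#' Read and write tab-separated tables
#'
#' Thin TSV round-trip helpers used for all tabular artifacts of the
#' pipeline (profile tables, peak tables, score tables, wide LFQ matrices).
#' Missing values are written as empty fields.
#'
#' @param x A data frame.
#' @param path File path.
#' @return `write_tsv_file()` returns `path` invisibly; `read_tsv_file()`
#'   returns a tibble.
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, na = ""
  )
  invisible(path)
}

#' @rdname write_tsv_file
#' @export
read_tsv_file <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tibble::as_tibble(utils::read.delim(path, na.strings = "", stringsAsFactors = FALSE))
}

#' Read and write FASTA sequence files
#'
#' @param sequences Named character vector of sequences.
#' @param path File path.
#' @return `write_fasta()` returns `path` invisibly; `read_fasta()` returns
#'   a named character vector.
#' @export
write_fasta <- function(sequences, path) {
  sequences <- as_named_sequences(sequences)
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(sequences), path
  )
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
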