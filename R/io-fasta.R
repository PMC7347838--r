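#' Read a FASTA file into a named character vector
#'
#' Sequences are returned exactly as stored in the file: record order and
#' character case are preserved (lowercase soft-masking survives a
#' round-trip). Only `N` is treated as a gap character elsewhere in the
#' package.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record. Names are the
#'   full header lines (without `>`).
#' @export
read_fasta <- function(path) {
  fail_if(!file.exists(path), "FASTA file not found: %s", path)
  x <- Biostrings::readBStringSet(path)
  ids <- names(x)
  fail_if(any(!nzchar(trimws(ids))), "FASTA record with empty header in %s", path)
  dup <- unique(ids[duplicated(ids)])
  fail_if(length(dup) > 0, "duplicate FASTA id(s): %s", paste(dup, collapse = ", "))
  stats::setNames(as.character(x), ids)
}

#' Write sequences to a FASTA file
#'
#' Sequences are wrapped at 60 columns; case is preserved.
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  dup <- unique(names(sequences)[duplicated(names(sequences))])
  fail_if(length(dup) > 0, "duplicate sequence id(s): %s", paste(dup, collapse = ", "))
  x <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}
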