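#' Reverse complement of a nucleotide string
#'
#' Complements A/C/G/T (and N) in both cases and reverses the string.
#' Characters outside the alphabet are left unchanged (then reversed).
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTn")
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Sequence lengths of a named sequence set
#'
#' @param sequences Named character vector of sequences.
#' @return Named integer vector of lengths.
#' @export
seq_lengths <- function(sequences) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  stats::setNames(nchar(sequences), names(sequences))
}

#' Locate runs of N (assembly gaps) in sequences
#'
#' Scans each sequence for maximal runs of the gap character `N`
#' (case-insensitive) and reports them in 0-based half-open coordinates.
#'
#' @param sequences Named character vector of sequences.
#' @return data.frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open) and `width`.
#' @export
#' @examples
#' n_run_ranges(c(s = "ACGTNNNNAC"))
n_run_ranges <- function(sequences) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  out <- lapply(names(sequences), function(id) {
    m <- gregexpr("[Nn]+", sequences[[id]])[[1]]
    if (m[1] == -1L) {
      return(data.frame(seq_id = character(0), start = integer(0),
                        end = integer(0), width = integer(0)))
    }
    w <- attr(m, "match.length")
    data.frame(seq_id = id, start = as.integer(m) - 1L,
               end = as.integer(m) - 1L + w, width = w)
  })
  do.call(rbind, out)
}

# internal: run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# internal: stopifnot with sprintf-style message
fail_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}
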