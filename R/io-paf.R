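paf_cols <- c("qname", "qlen", "qstart", "qend", "strand",
              "tname", "tlen", "tstart", "tend", "nmatch", "blocklen", "mapq")
paf_int_cols <- setdiff(paf_cols, c("qname", "strand", "tname"))

#' Construct a table of pairwise alignment records
#'
#' The in-memory alignment container used throughout the package: one row
#' per query-to-target alignment with the 12 mandatory PAF columns.
#' Coordinates are 0-based half-open; minus-strand records keep both query
#' and target coordinates on the forward strand, per the PAF convention.
#'
#' @param df data.frame with columns `qname, qlen, qstart, qend, strand,
#'   tname, tlen, tstart, tend, nmatch, blocklen, mapq`.
#' @return Validated data.frame of class `paf`.
#' @export
paf_records <- function(df) {
  fail_if(!all(paf_cols %in% names(df)),
          "missing alignment columns: %s",
          paste(setdiff(paf_cols, names(df)), collapse = ", "))
  df <- df[, paf_cols, drop = FALSE]
  for (cc in paf_int_cols) df[[cc]] <- as.numeric(df[[cc]])
  df$qname <- as.character(df$qname)
  df$tname <- as.character(df$tname)
  df$strand <- as.character(df$strand)
  if (nrow(df) > 0) {
    fail_if(any(!df$strand %in% c("+", "-")), "strand must be '+' or '-'")
    bad <- !(df$qstart >= 0 & df$qstart < df$qend & df$qend <= df$qlen)
    fail_if(any(bad), "invalid query coordinates for: %s",
            paste(utils::head(df$qname[bad]), collapse = ", "))
    bad <- !(df$tstart >= 0 & df$tstart < df$tend & df$tend <= df$tlen)
    fail_if(any(bad), "invalid target coordinates for: %s",
            paste(utils::head(df$qname[bad]), collapse = ", "))
    fail_if(any(df$nmatch > df$blocklen), "nmatch exceeds block length")
    fail_if(any(df$mapq < 0 | df$mapq > 255), "mapq outside [0, 255]")
  }
  rownames(df) <- NULL
  class(df) <- c("paf", "data.frame")
  df
}

#' Read alignments from a PAF file
#'
#' Parses the 12 mandatory tab-separated columns; optional SAM-style tags
#' beyond column 12 are ignored. Coordinates are kept 0-based half-open.
#'
#' @param path Path to a PAF file.
#' @return Alignment table (see [paf_records()]).
#' @export
read_paf <- function(path) {
  fail_if(!file.exists(path), "PAF file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(paf_records(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = 12)), paf_cols)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  fail_if(any(nf < 12), "PAF line %d has %d columns (12 required)",
          which(nf < 12)[1], nf[which(nf < 12)[1]])
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  df <- stats::setNames(as.data.frame(m, stringsAsFactors = FALSE), paf_cols)
  for (cc in paf_int_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    fail_if(anyNA(v), "non-numeric value in PAF column '%s' at line %d",
            cc, which(is.na(v))[1])
    df[[cc]] <- v
  }
  paf_records(df)
}

#' Write alignments to a PAF file
#'
#' Emits the 12 mandatory columns, tab-separated. Round-trips with
#' [read_paf()] bit-exactly.
#'
#' @param aln Alignment table (see [paf_records()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(aln, path) {
  aln <- paf_records(aln)
  fmt <- aln
  for (cc in paf_int_cols) fmt[[cc]] <- format(fmt[[cc]], scientific = FALSE, trim = TRUE)
  lines <- do.call(paste, c(unname(as.list(fmt[, paf_cols])), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
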