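# Assembly statistics, telomere-motif detection and linkage-map
# concordance checks.

#' Assembly contiguity statistics
#'
#' N50 is the length of the shortest sequence in the smallest set of
#' longest sequences jointly covering at least half of the total bases;
#' L50 is that set's size. Gaps are maximal N-runs.
#'
#' @param sequences Named character vector (non-empty).
#' @return List: `n_seq`, `total_bases`, `n50`, `l50`, `gap_count`,
#'   `gap_bases`, `max_len`.
#' @export
contig_stats <- function(sequences) {
  fail_if(length(sequences) == 0, "empty sequence set")
  lens <- sort(seq_lengths(sequences), decreasing = TRUE)
  cum <- cumsum(as.numeric(lens))
  l50 <- which(cum >= sum(as.numeric(lens)) / 2)[1]
  runs <- n_run_ranges(sequences)
  list(n_seq = length(lens), total_bases = sum(as.numeric(lens)),
       n50 = unname(lens[l50]), l50 = unname(l50),
       gap_count = nrow(runs), gap_bases = sum(runs$width),
       max_len = unname(lens[1]))
}

#' Detect terminal telomeric repeat arrays
#'
#' Scans the first and last `window` bases of each sequence for tandem
#' arrays of `motif` or its reverse complement: at least `min_units`
#' copies with at most one unit-length interruption between consecutive
#' copies. For the vertebrate telomeric repeat the forward-strand motif
#' at the 5' end is `CCCTAA` and its reverse complement `TTAGGG` appears
#' at the 3' end.
#'
#' @param sequences Named character vector.
#' @param motif Repeat unit (default `"CCCTAA"`).
#' @param window Terminal window searched at each end (bp).
#' @param min_units Minimum tandem copies.
#' @return data.frame: `seq_id`, `end` (`5prime`/`3prime`), `strand`
#'   (`forward` = motif, `reverse` = reverse complement), `units`,
#'   `offset` (0-based array start within the window, from the respective
#'   end).
#' @export
detect_telomeric_repeats <- function(sequences, motif = "CCCTAA",
                                     window = 10000, min_units = 3) {
  fail_if(!nzchar(motif), "motif must be non-empty")
  fail_if(window < nchar(motif) * min_units,
          "window smaller than min_units copies of the motif")
  ulen <- nchar(motif)
  motifs <- c(forward = toupper(motif), reverse = revcomp(toupper(motif)))
  hits <- list()
  scan_window <- function(txt) {
    # tandem arrays per strand variant: chain matches 1 or 2 units apart
    out <- list()
    for (strand in names(motifs)) {
      m <- gregexpr(motifs[[strand]], toupper(txt), fixed = TRUE)[[1]]
      if (m[1] == -1L) next
      starts <- as.integer(m) - 1L
      grp <- cumsum(c(1, diff(starts) > 2 * ulen))
      for (g in unique(grp)) {
        s <- starts[grp == g]
        if (length(s) >= min_units) {
          out[[length(out) + 1L]] <- data.frame(
            strand = strand, units = length(s), offset = s[1],
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  for (id in names(sequences)) {
    s <- sequences[[id]]
    len <- nchar(s)
    w <- min(window, len)
    for (end in c("5prime", "3prime")) {
      txt <- if (end == "5prime") substring(s, 1, w) else
        substring(s, len - w + 1, len)
      h <- scan_window(txt)
      if (!is.null(h)) {
        h <- cbind(seq_id = id, end = end, h)
        hits[[length(hits) + 1L]] <- h
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(seq_id = character(0), end = character(0),
                      strand = character(0), units = integer(0),
                      offset = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Linkage-map concordance and scaffold orientation
#'
#' Compares each marker's linkage group against its assembled chromosome.
#' When no explicit group-to-chromosome map is given, the correspondence
#' is inferred by majority vote (the chromosome holding most of a group's
#' markers). Concordance is reported as a percentage rounded to two
#' decimals. Per chromosome, orientation is `+` when genetic (cM) and
#' physical (bp) marker orders correlate positively (Kendall tau over the
#' concordant markers), `-` when negatively, and `unknown` with fewer
#' than 3 markers or tau exactly 0.
#'
#' @param placements data.frame: `marker_id`, `linkage_group`, `cM`,
#'   `chrom`, `pos`, optional `mapq`.
#' @param group_map Optional named character vector, linkage group ->
#'   chromosome.
#' @param chrom_lengths Optional named lengths used to validate marker
#'   chromosomes/positions.
#' @return List: `n_markers`, `n_concordant`, `concordance_pct`,
#'   `discordance_pct` (both rounded to 2 decimals), `discordant`
#'   (data.frame of discordant markers), `orientation` (data.frame
#'   `chrom`, `tau`, `orientation`), `group_map`.
#' @export
linkage_concordance <- function(placements, group_map = NULL,
                                chrom_lengths = NULL) {
  fail_if(nrow(placements) == 0, "no marker placements")
  if (!is.null(chrom_lengths)) {
    bad <- !placements$chrom %in% names(chrom_lengths)
    fail_if(any(bad), "marker %s references unknown chromosome %s",
            placements$marker_id[which(bad)[1]], placements$chrom[which(bad)[1]])
    fail_if(any(placements$pos < 0 |
                  placements$pos >= chrom_lengths[placements$chrom]),
            "marker position outside chromosome")
  }
  if (is.null(group_map)) {
    group_map <- vapply(split(placements$chrom, placements$linkage_group),
                        function(ch) names(which.max(table(ch))), character(1))
  }
  known <- placements$linkage_group %in% names(group_map)
  concordant <- known & placements$chrom == group_map[placements$linkage_group]
  n <- nrow(placements)
  pct <- round(100 * sum(concordant) / n, 2)
  orientation <- do.call(rbind, lapply(unique(placements$chrom), function(ch) {
    m <- placements[placements$chrom == ch & concordant, , drop = FALSE]
    if (nrow(m) < 3) {
      return(data.frame(chrom = ch, tau = NA_real_, orientation = "unknown",
                        stringsAsFactors = FALSE))
    }
    tau <- suppressWarnings(stats::cor(m$pos, m$cM, method = "kendall"))
    ornt <- if (is.na(tau) || tau == 0) "unknown" else if (tau > 0) "+" else "-"
    data.frame(chrom = ch, tau = tau, orientation = ornt,
               stringsAsFactors = FALSE)
  }))
  list(n_markers = n, n_concordant = sum(concordant),
       concordance_pct = pct, discordance_pct = round(100 - pct, 2),
       discordant = placements[!concordant, , drop = FALSE],
       orientation = orientation, group_map = group_map)
}
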