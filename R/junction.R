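# Junction validation by spanning long-read support.
#
# A junction is an inter-base coordinate inside an assembly sequence. A
# read supports it when a single alignment covers the junction with at
# least `min_flank` aligned bases on BOTH sides at mapping quality >=
# `min_mapq`. Junctions below `min_spanning_reads` supporting reads are
# split.

#' Junction validation policy
#'
#' Defaults follow the curation rule of requiring at least one confidently
#' mapped (MQ60) long read overlapping a junction by a minimum of 100 bp
#' on each side.
#'
#' @param min_flank Minimum aligned bases on each side of the junction (bp).
#' @param min_mapq Minimum mapping quality of a supporting read.
#' @param min_spanning_reads Support threshold for a `supported` verdict.
#' @return List of class `junction_policy`.
#' @export
junction_policy <- function(min_flank = 100, min_mapq = 60,
                            min_spanning_reads = 1) {
  stopifnot(min_flank > 0, min_mapq >= 0, min_mapq <= 255,
            min_spanning_reads >= 1)
  structure(list(min_flank = min_flank, min_mapq = min_mapq,
                 min_spanning_reads = min_spanning_reads),
            class = "junction_policy")
}

#' Enumerate candidate junctions in an assembly
#'
#' Three universes are supported:
#' * `"gaps"`: both flanks of every N-run (the boundaries where contigs
#'   meet a scaffold gap);
#' * `"breakpoints"`: user-supplied positions, e.g. unverified collinearity
#'   breakpoints from [verify_collinearity()];
#' * `"tiling"`: every `step`-th inter-base position.
#'
#' @param sequences Named character vector (the assembly).
#' @param mode One of `"gaps"`, `"breakpoints"`, `"tiling"`.
#' @param breakpoints data.frame with `seq_id`, `pos` (breakpoints mode).
#' @param step Tiling step (bp, > 0).
#' @return data.frame: `seq_id`, `pos` (0-based inter-base coordinate).
#' @export
enumerate_junctions <- function(sequences, mode = c("gaps", "breakpoints", "tiling"),
                                breakpoints = NULL, step = NULL) {
  mode <- match.arg(mode)
  if (mode == "gaps") {
    runs <- n_run_ranges(sequences)
    out <- data.frame(seq_id = rep(runs$seq_id, 2),
                      pos = c(runs$start, runs$end))
    out <- out[order(out$seq_id, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  if (mode == "breakpoints") {
    fail_if(is.null(breakpoints), "breakpoints mode needs a breakpoints table")
    stopifnot(all(c("seq_id", "pos") %in% names(breakpoints)))
    return(breakpoints[c("seq_id", "pos")])
  }
  fail_if(is.null(step) || step <= 0, "tiling mode needs step > 0")
  lens <- seq_lengths(sequences)
  out <- do.call(rbind, lapply(names(lens), function(id) {
    pos <- seq(step, lens[[id]] - 1, by = step)
    if (length(pos) == 0) return(NULL)
    data.frame(seq_id = id, pos = pos, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) out <- data.frame(seq_id = character(0), pos = numeric(0))
  out
}

#' Compute spanning-read support for junctions
#'
#' @param junctions data.frame with `seq_id`, `pos`.
#' @param alignments Alignment table of reads mapped to the assembly under
#'   test (`tname` = assembly sequence id).
#' @param policy A [junction_policy()].
#' @param lengths Optional named vector of sequence lengths for coordinate
#'   validation (defaults to `tlen` values seen in `alignments`).
#' @return data.frame: `seq_id`, `pos`, `support`, `verdict`
#'   (`supported`/`split`).
#' @export
compute_span_support <- function(junctions, alignments,
                                 policy = junction_policy(), lengths = NULL) {
  stopifnot(inherits(policy, "junction_policy"))
  if (is.null(lengths) && nrow(alignments) > 0) {
    lengths <- tapply(alignments$tlen, alignments$tname, max)
  }
  if (!is.null(lengths)) {
    known <- junctions$seq_id %in% names(lengths)
    bad <- known & (junctions$pos <= 0 |
                      junctions$pos >= lengths[junctions$seq_id])
    fail_if(any(bad), "junction outside sequence: %s:%s",
            junctions$seq_id[which(bad)[1]], junctions$pos[which(bad)[1]])
  }
  ok <- alignments[alignments$mapq >= policy$min_mapq, , drop = FALSE]
  support <- vapply(seq_len(nrow(junctions)), function(i) {
    a <- ok[ok$tname == junctions$seq_id[i], , drop = FALSE]
    pos <- junctions$pos[i]
    sum(a$tstart <= pos - policy$min_flank & a$tend >= pos + policy$min_flank)
  }, numeric(1))
  data.frame(seq_id = junctions$seq_id, pos = junctions$pos,
             support = support,
             verdict = ifelse(support >= policy$min_spanning_reads,
                              "supported", "split"),
             stringsAsFactors = FALSE)
}

#' Split assembly sequences at unsupported junctions
#'
#' Every junction with verdict `split` becomes a sequence boundary. A split
#' position falling on (or inside) an N-run removes the whole run from the
#' output pieces; several split positions on one N-run collapse to a single
#' split with a warning. Pieces are named `<old_id>.1`, `.2`, ... from left
#' to right; sequences without splits keep their id. The returned log
#' records every piece and every removed gap, so the input can be
#' reassembled byte-exactly.
#'
#' @param sequences Named character vector (the assembly).
#' @param calls data.frame from [compute_span_support()].
#' @return List:
#'   * `sequences`: the split assembly;
#'   * `log`: data.frame `old_id`, `new_id`, `start`, `end` (0-based
#'     half-open piece coordinates on the old sequence), `gap_after`
#'     (length of the N-run removed after this piece, 0 if none).
#' @export
split_unsupported <- function(sequences, calls) {
  splits <- calls[calls$verdict == "split", , drop = FALSE]
  out_seq <- character(0)
  log <- list()
  for (id in names(sequences)) {
    s <- sequences[[id]]
    len <- nchar(s)
    pos <- sort(unique(splits$pos[splits$seq_id == id]))
    if (length(pos) == 0) {
      out_seq[id] <- s
      log[[length(log) + 1L]] <- data.frame(
        old_id = id, new_id = id, start = 0, end = len, gap_after = 0,
        stringsAsFactors = FALSE)
      next
    }
    runs <- n_run_ranges(stats::setNames(s, id))
    # map each split position to its N-run (if it touches one)
    run_of <- vapply(pos, function(p) {
      hit <- which(runs$start <= p & p <= runs$end)
      if (length(hit)) hit[1] else NA_integer_
    }, integer(1))
    if (anyDuplicated(stats::na.omit(run_of))) {
      warning(sprintf("multiple split positions on one N-run of %s; collapsed", id))
    }
    # each split is an interval to excise: [start,end) of the N-run, or a
    # zero-width cut at the position itself
    cuts <- unique(do.call(rbind, lapply(seq_along(pos), function(k) {
      if (is.na(run_of[k])) c(pos[k], pos[k])
      else c(runs$start[run_of[k]], runs$end[run_of[k]])
    })))
    cuts <- cuts[order(cuts[, 1]), , drop = FALSE]
    bounds <- c(0, as.vector(t(cuts)), len)
    starts <- bounds[seq(1, length(bounds) - 1, by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    gap_after <- c(cuts[, 2] - cuts[, 1], 0)
    keep <- ends > starts
    starts <- starts[keep]; ends <- ends[keep]; gap_after <- gap_after[keep]
    for (k in seq_along(starts)) {
      nid <- sprintf("%s.%d", id, k)
      out_seq[nid] <- substring(s, starts[k] + 1, ends[k])
      log[[length(log) + 1L]] <- data.frame(
        old_id = id, new_id = nid, start = starts[k], end = ends[k],
        gap_after = gap_after[k], stringsAsFactors = FALSE)
    }
  }
  list(sequences = out_seq, log = do.call(rbind, log))
}
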