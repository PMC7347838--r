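# In-silico size selection of gel-free mate-pair libraries.
#
# Orientation convention (configurable): after mapping, paired-end
# contaminant reads face each other ("inward", FR), true circularization
# mate pairs face away from each other ("outward", RF). The insert is the
# outer distance on the target.

#' Classify mapped read pairs as mate-pair, paired-end, ambiguous or unusable
#'
#' Operates on an alignment table whose query names end in `/1` and `/2`
#' (one primary alignment per mate). A pair is classified from the relative
#' orientation of its mates on the target:
#'
#' * both mates on one target, non-overlapping, facing away from each other
#'   -> `MP` (true mate pair under the default `mp_orientation = "outward"`);
#' * facing toward each other -> `PE` (small-insert contaminant);
#' * same strand, different targets, or overlapping mates -> `ambiguous`;
#' * a mate missing or below `min_mapq` -> `unusable`.
#'
#' The insert is the outer span `max(tend) - min(tstart)`; it is reported
#' only for `MP`/`PE` pairs. Classification is symmetric in mate order.
#'
#' @param aln Alignment table (see [paf_records()]) with `/1`,`/2` suffixes.
#' @param min_mapq Minimum mapping quality per mate (default 20).
#' @param mp_orientation Which orientation is the true mate pair:
#'   `"outward"` (default, circularization chemistry) or `"inward"`.
#' @return data.frame: `pair_id`, `class` (`MP`,`PE`,`ambiguous`,`unusable`),
#'   `insert` (NA unless MP/PE), `tname`.
#' @export
classify_pairs <- function(aln, min_mapq = 20, mp_orientation = c("outward", "inward")) {
  mp_orientation <- match.arg(mp_orientation)
  stopifnot(min_mapq >= 0, min_mapq <= 255)
  fail_if(!all(grepl("/[12]$", aln$qname)),
          "pair alignments must have qname suffix /1 or /2")
  pid <- sub("/[12]$", "", aln$qname)
  mate <- sub("^.*/", "", aln$qname)
  ids <- unique(pid)
  m1 <- match(paste0(ids, "/1"), aln$qname)
  m2 <- match(paste0(ids, "/2"), aln$qname)
  has_both <- !is.na(m1) & !is.na(m2)
  ok_mapq <- has_both & aln$mapq[m1] >= min_mapq & aln$mapq[m2] >= min_mapq
  same_t <- has_both & aln$tname[m1] == aln$tname[m2]
  lo_first <- ifelse(same_t & aln$tstart[m1] <= aln$tstart[m2], m1, m2)
  hi_last <- ifelse(same_t & aln$tstart[m1] <= aln$tstart[m2], m2, m1)
  s_lo <- aln$strand[lo_first]; s_hi <- aln$strand[hi_last]
  overlapping <- same_t & aln$tend[lo_first] > aln$tstart[hi_last]
  inward <- s_lo == "+" & s_hi == "-"
  outward <- s_lo == "-" & s_hi == "+"
  facing <- ifelse(inward, "inward", ifelse(outward, "outward", "same"))
  cls <- rep("ambiguous", length(ids))
  cls[!ok_mapq] <- "unusable"
  usable <- ok_mapq & same_t & !overlapping & facing != "same"
  cls[usable & facing == mp_orientation] <- "MP"
  cls[usable & facing != mp_orientation] <- "PE"
  insert <- ifelse(cls %in% c("MP", "PE"),
                   pmax(aln$tend[m1], aln$tend[m2]) -
                     pmin(aln$tstart[m1], aln$tstart[m2]),
                   NA_real_)
  data.frame(pair_id = ids, class = cls, insert = insert,
             tname = ifelse(same_t, aln$tname[m1], NA_character_),
             stringsAsFactors = FALSE)
}

#' Classify a single read pair
#'
#' Convenience wrapper over [classify_pairs()] for two alignment rows of
#' one pair.
#'
#' @param a1,a2 Single-row alignment tables for mate 1 and mate 2; their
#'   query names must share the pair id (suffixes `/1`, `/2` optional).
#' @param ... Passed to [classify_pairs()].
#' @return One-row classification data.frame.
#' @export
classify_pair <- function(a1, a2, ...) {
  id1 <- sub("/[12]$", "", a1$qname)
  id2 <- sub("/[12]$", "", a2$qname)
  fail_if(id1 != id2, "mates belong to different pairs: %s vs %s", id1, id2)
  a1$qname <- paste0(id1, "/1")
  a2$qname <- paste0(id2, "/2")
  classify_pairs(rbind(a1, a2), ...)
}

#' Bin classified pairs by insert size
#'
#' Sorts MP/PE pairs into half-open insert-size bins `[e_i, e_{i+1})`
#' defined by ascending edges — the in-silico analogue of gel size
#' selection. Pairs below the first or at/above the last edge go to
#' discard buckets; ambiguous and unusable pairs are ledgered separately,
#' so `sum(counts) == nrow(pairs)` always holds exactly.
#'
#' @param pairs Classification data.frame from [classify_pairs()].
#' @param edges Strictly ascending numeric vector of bin edges (>= 2).
#' @return List:
#'   * `assignments`: `pair_id`, `class`, `insert`, `bin`;
#'   * `stats`: per-bucket `bin`, `count`, `median`, `mad` (insert median
#'     and median absolute deviation; NA for empty/non-insert buckets).
#' @export
bin_by_insert <- function(pairs, edges) {
  fail_if(length(edges) < 2, "need at least two bin edges")
  fail_if(any(diff(edges) <= 0), "bin edges must be strictly ascending")
  bins <- paste0("[", edges[-length(edges)], ",", edges[-1], ")")
  bucket <- rep(NA_character_, nrow(pairs))
  bucket[pairs$class == "ambiguous"] <- "ambiguous"
  bucket[pairs$class == "unusable"] <- "unusable"
  sized <- pairs$class %in% c("MP", "PE")
  idx <- findInterval(pairs$insert[sized], edges)
  bucket[sized] <- ifelse(idx == 0, "discard_low",
                          ifelse(idx == length(edges), "discard_high",
                                 bins[idx]))
  levels <- c(bins, "discard_low", "discard_high", "ambiguous", "unusable")
  stats <- do.call(rbind, lapply(levels, function(b) {
    ins <- pairs$insert[which(bucket == b)]
    data.frame(bin = b, count = length(ins),
               median = if (length(ins)) stats::median(ins) else NA_real_,
               mad = if (length(ins)) stats::mad(ins) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  stopifnot(sum(stats$count) == nrow(pairs)) # conservation ledger
  list(assignments = cbind(pairs[c("pair_id", "class", "insert")],
                           bin = bucket),
       stats = stats)
}
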