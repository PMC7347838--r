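# Detection and merging of large end overlaps between neighboring contigs
# within scaffolds. Detection is exact k-mer seeding (default k = 15)
# between the left contig's terminal suffix window and the right contig's
# prefix window, followed by ungapped evaluation of every candidate
# overlap length implied by a seed diagonal.

kmer_starts <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(integer(0))
  seq_len(n - k + 1)
}

#' Find end overlaps between neighboring contigs
#'
#' For each neighboring pair in a scaffold layout, searches for the
#' best-scoring overlap between the end of the left contig and the start
#' of the right contig inside terminal windows of `max_search` bp. Seed
#' k-mers shared between the windows propose candidate overlap lengths;
#' each candidate is scored by ungapped identity over the full overlap.
#' At most one candidate (the best by matches, then identity) is reported
#' per pair, and only if it reaches `min_len` and `min_identity`.
#'
#' @param neighbors data.frame with columns `left_id`, `right_id`, one row
#'   per neighboring contig pair, in scaffold order.
#' @param sequences Named character vector of contig sequences (already in
#'   scaffold orientation).
#' @param max_search Terminal window size (bp).
#' @param min_len Minimum overlap length (bp).
#' @param min_identity Minimum overlap identity in `[0, 1]`.
#' @param k Seed k-mer size.
#' @return data.frame: `left_id`, `right_id`, `overlap_len`, `identity`,
#'   `matches`. Pairs with a contig shorter than `min_len` are skipped.
#' @export
find_end_overlaps <- function(neighbors, sequences, max_search = 20000,
                              min_len = 100, min_identity = 0.99, k = 15) {
  stopifnot(max_search >= min_len, min_len >= k)
  out <- list()
  for (i in seq_len(nrow(neighbors))) {
    lid <- neighbors$left_id[i]; rid <- neighbors$right_id[i]
    ls <- toupper(sequences[[lid]]); rs <- toupper(sequences[[rid]])
    ll <- nchar(ls); rl <- nchar(rs)
    if (ll < min_len || rl < min_len) next
    m <- min(max_search, ll)
    w1 <- substring(ls, ll - m + 1, ll)       # left suffix window
    w2 <- substring(rs, 1, min(max_search, rl)) # right prefix window
    p1 <- kmer_starts(w1, k); p2 <- kmer_starts(w2, k)
    if (length(p1) == 0 || length(p2) == 0) next
    k1 <- substring(w1, p1, p1 + k - 1)
    k2 <- substring(w2, p2, p2 + k - 1)
    # drop hyper-repetitive seeds to bound the candidate set
    t2 <- table(k2)
    common <- intersect(k1, names(t2)[t2 <= 10])
    t1 <- table(k1)
    common <- intersect(common, names(t1)[t1 <= 10])
    if (length(common) == 0) next
    cand <- unique(unlist(lapply(common, function(km) {
      i1 <- p1[k1 == km]; j2 <- p2[k2 == km]
      as.vector(outer(m - i1 + 1, j2 - 1, "+")) # overlap length L = m - i + j
    })))
    cand <- cand[cand >= min_len & cand <= min(ll, rl, max_search)]
    if (length(cand) == 0) next
    best <- NULL
    for (L in sort(cand, decreasing = TRUE)) {
      a <- utf8ToInt(substring(ls, ll - L + 1, ll))
      b <- utf8ToInt(substring(rs, 1, L))
      matches <- sum(a == b)
      ident <- matches / L
      if (is.null(best) || matches > best$matches ||
          (matches == best$matches && ident > best$identity)) {
        best <- list(L = L, matches = matches, identity = ident)
      }
    }
    if (best$identity >= min_identity && best$L >= min_len) {
      out[[length(out) + 1L]] <- data.frame(
        left_id = lid, right_id = rid, overlap_len = best$L,
        identity = best$identity, matches = best$matches,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(left_id = character(0), right_id = character(0),
                      overlap_len = numeric(0), identity = numeric(0),
                      matches = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Merge overlapping neighboring contigs
#'
#' Applies overlap candidates left-to-right along the scaffold layout.
#' The merged sequence keeps the left contig's bases inside the overlap
#' (no base-quality model is available to arbitrate); all bases outside
#' the overlap are preserved verbatim, so the merged length is
#' `len(left) + len(right) - overlap`. Chained overlaps (A-B and B-C)
#' are applied sequentially: the merged contig keeps the leftmost id and
#' stands in for its parts in later joins. If two candidates touch the
#' same contig end, the higher-identity (then longer) one is applied and
#' the other is logged as skipped.
#'
#' @param neighbors data.frame `left_id`, `right_id` in scaffold order.
#' @param sequences Named character vector of contig sequences.
#' @param candidates Output of [find_end_overlaps()] on the same layout.
#' @return List:
#'   * `sequences`: updated contig set (merged contigs replace their
#'     parts, keeping the leftmost id);
#'   * `log`: data.frame `left_id`, `right_id`, `overlap_len`, `identity`,
#'     `merged_id`, `merged_len`, `applied`, `reason`.
#' @export
join_overlapping_contigs <- function(neighbors, sequences, candidates) {
  seqs <- sequences
  alias <- stats::setNames(names(sequences), names(sequences))
  log <- list()
  if (nrow(candidates) > 0) {
    # resolve conflicts on a shared contig end: higher identity, then longer
    ord <- order(candidates$identity, candidates$overlap_len, decreasing = TRUE)
    seen_left <- character(0); seen_right <- character(0)
    keep <- logical(nrow(candidates))
    for (k in ord) {
      if (candidates$left_id[k] %in% seen_left ||
          candidates$right_id[k] %in% seen_right) next
      keep[k] <- TRUE
      seen_left <- c(seen_left, candidates$left_id[k])
      seen_right <- c(seen_right, candidates$right_id[k])
    }
    skipped <- candidates[!keep, , drop = FALSE]
    for (k in seq_len(nrow(skipped))) {
      log[[length(log) + 1L]] <- data.frame(
        left_id = skipped$left_id[k], right_id = skipped$right_id[k],
        overlap_len = skipped$overlap_len[k], identity = skipped$identity[k],
        merged_id = NA_character_, merged_len = NA_real_, applied = FALSE,
        reason = "conflicting_candidate", stringsAsFactors = FALSE)
    }
    candidates <- candidates[keep, , drop = FALSE]
  }
  # apply in layout order
  for (i in seq_len(nrow(neighbors))) {
    hit <- which(candidates$left_id == neighbors$left_id[i] &
                   candidates$right_id == neighbors$right_id[i])
    if (length(hit) == 0) next
    cc <- candidates[hit[1], ]
    lcur <- alias[[cc$left_id]]; rcur <- alias[[cc$right_id]]
    ls <- seqs[[lcur]]; rs <- seqs[[rcur]]
    L <- cc$overlap_len
    merged <- paste0(ls, substring(rs, L + 1, nchar(rs)))
    seqs <- seqs[!names(seqs) %in% c(lcur, rcur)]
    seqs[lcur] <- merged
    alias[alias == rcur] <- lcur
    log[[length(log) + 1L]] <- data.frame(
      left_id = cc$left_id, right_id = cc$right_id, overlap_len = L,
      identity = cc$identity, merged_id = lcur, merged_len = nchar(merged),
      applied = TRUE, reason = NA_character_, stringsAsFactors = FALSE)
  }
  list(sequences = seqs,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(left_id = character(0), right_id = character(0),
                    overlap_len = numeric(0), identity = numeric(0),
                    merged_id = character(0), merged_len = numeric(0),
                    applied = logical(0), reason = character(0),
                    stringsAsFactors = FALSE))
  }
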