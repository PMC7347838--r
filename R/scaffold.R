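# Long-read scaffolding: contig-end link graph, reference-synteny guard,
# greedy linearization into simple paths.

node_id <- function(contig, end) paste0(contig, ":", end)

#' Build a contig-end link graph from long-read alignments
#'
#' A read links two contig ends when it aligns to both contigs, each
#' alignment reaching within `end_window` of the respective end, with the
#' contig ends implied by read order and alignment strands. The implied
#' gap of a link is the unaligned read distance between the two alignments
#' minus the unaligned contig overhangs (negative values mean the contigs
#' overlap).
#'
#' @param alignments Alignment table of reads vs contigs.
#' @param contig_lengths Named vector of contig lengths.
#' @param end_window How close (bp) an alignment must come to a contig end
#'   to imply linkage.
#' @param min_reads Minimum supporting reads per retained edge (the
#'   curation default is 1: a single confidently mapped long read
#'   suffices).
#' @return List of class `link_graph`: `edges` (data.frame `contig1, end1,
#'   contig2, end2, support`, list-columns `reads`, `gaps`) and `contigs`
#'   (the length vector).
#' @export
build_link_graph <- function(alignments, contig_lengths, end_window = 1000,
                             min_reads = 1) {
  stopifnot(end_window > 0, min_reads >= 1)
  links <- list()
  multi <- alignments$qname[duplicated(alignments$qname)]
  a <- alignments[alignments$qname %in% multi, , drop = FALSE]
  for (rid in unique(a$qname)) {
    r <- a[a$qname == rid, , drop = FALSE]
    r <- r[order(r$qstart), , drop = FALSE]
    for (i in seq_len(nrow(r) - 1)) {
      x <- r[i, ]; y <- r[i + 1, ]
      if (x$tname == y$tname) next
      exit_end <- if (x$strand == "+") "tail" else "head"
      entry_end <- if (y$strand == "+") "head" else "tail"
      over_x <- if (x$strand == "+") x$tlen - x$tend else x$tstart
      over_y <- if (y$strand == "+") y$tstart else y$tlen - y$tend
      if (over_x > end_window || over_y > end_window) next
      gap <- (y$qstart - x$qend) - over_x - over_y
      n1 <- c(x$tname, exit_end); n2 <- c(y$tname, entry_end)
      if (n1[1] > n2[1]) { tmp <- n1; n1 <- n2; n2 <- tmp }
      key <- paste(n1[1], n1[2], n2[1], n2[2])
      if (is.null(links[[key]])) {
        links[[key]] <- list(contig1 = n1[1], end1 = n1[2],
                             contig2 = n2[1], end2 = n2[2],
                             reads = character(0), gaps = numeric(0))
      }
      links[[key]]$reads <- c(links[[key]]$reads, rid)
      links[[key]]$gaps <- c(links[[key]]$gaps, gap)
    }
  }
  edges <- if (length(links) == 0) {
    data.frame(contig1 = character(0), end1 = character(0),
               contig2 = character(0), end2 = character(0),
               support = integer(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(unname(links), function(l) {
      data.frame(contig1 = l$contig1, end1 = l$end1, contig2 = l$contig2,
                 end2 = l$end2, support = length(l$reads),
                 stringsAsFactors = FALSE)
    }))
  }
  edges$reads <- lapply(unname(links), `[[`, "reads")
  edges$gaps <- lapply(unname(links), `[[`, "gaps")
  edges <- edges[edges$support >= min_reads, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, contigs = contig_lengths,
                 removed = NULL), class = "link_graph")
}

#' Filter link-graph edges against reference synteny
#'
#' Drops edges that would violate chromosomal synteny of a guiding
#' reference: links between contigs anchored to different reference
#' chromosomes, and links between same-chromosome contigs that skip over
#' another anchored contig lying strictly between them. Edges touching
#' unanchored contigs are given the benefit of the doubt and kept.
#' Filtering is idempotent.
#'
#' @param graph A `link_graph`.
#' @param guard data.frame with columns `contig`, `chrom`, `pos` (one
#'   anchor per contig; contigs absent from the table are unanchored).
#' @return The filtered `link_graph`; removed edges (with a `reason`) are
#'   appended to `$removed`.
#' @export
filter_links_by_synteny <- function(graph, guard) {
  stopifnot(inherits(graph, "link_graph"),
            all(c("contig", "chrom", "pos") %in% names(guard)))
  fail_if(anyDuplicated(guard$contig) > 0, "guard must have one anchor per contig")
  e <- graph$edges
  if (nrow(e) == 0) return(graph)
  i1 <- match(e$contig1, guard$contig)
  i2 <- match(e$contig2, guard$contig)
  anchored <- !is.na(i1) & !is.na(i2)
  reason <- rep(NA_character_, nrow(e))
  diff_chrom <- anchored & guard$chrom[i1] != guard$chrom[i2]
  reason[diff_chrom] <- "inter_chromosome"
  same <- which(anchored & !diff_chrom)
  for (k in same) {
    ch <- guard$chrom[i1[k]]
    lo <- min(guard$pos[i1[k]], guard$pos[i2[k]])
    hi <- max(guard$pos[i1[k]], guard$pos[i2[k]])
    between <- guard$chrom == ch & guard$pos > lo & guard$pos < hi &
      !guard$contig %in% c(e$contig1[k], e$contig2[k])
    if (any(between)) reason[k] <- "skipped_anchor"
  }
  drop <- !is.na(reason)
  removed <- cbind(e[drop, c("contig1", "end1", "contig2", "end2", "support")],
                   reason = reason[drop])
  graph$edges <- e[!drop, , drop = FALSE]
  rownames(graph$edges) <- NULL
  graph$removed <- rbind(graph$removed, removed)
  graph
}

#' Linearize a link graph into scaffold paths
#'
#' Greedy edge selection ordered by (support descending, gap-MAD
#' ascending, lexicographic node ids); an edge is accepted only if both
#' contig ends are still free and it does not close a cycle, so every
#' contig end has degree <= 1 and scaffolds are simple paths. Rejected
#' edges are logged with the reason. The gap estimate of a join is the
#' median of its implied gaps, floored at 10 when non-positive; joins with
#' median gap <= -50 are flagged as overlap candidates for
#' [find_end_overlaps()].
#'
#' @param graph A `link_graph`.
#' @return List:
#'   * `paths`: data.frame `scaffold, idx, contig, orientation,
#'     gap_before` (NA for the first contig of a scaffold);
#'   * `joins`: data.frame `left_contig, right_contig, support, gap_median,
#'     gap_est, overlap_candidate`;
#'   * `conflicts`: data.frame of rejected edges with `reason`.
#' @export
linearize_scaffolds <- function(graph) {
  stopifnot(inherits(graph, "link_graph"))
  e <- graph$edges
  conflicts <- NULL
  accepted <- NULL
  if (nrow(e) > 0) {
    gap_med <- vapply(e$gaps, stats::median, numeric(1))
    gap_mad <- vapply(e$gaps, stats::mad, numeric(1))
    ord <- order(-e$support, gap_mad,
                 node_id(e$contig1, e$end1), node_id(e$contig2, e$end2))
    used_end <- character(0)
    parent <- stats::setNames(names(graph$contigs), names(graph$contigs))
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    acc <- logical(nrow(e)); reason <- rep(NA_character_, nrow(e))
    for (k in ord) {
      n1 <- node_id(e$contig1[k], e$end1[k]); n2 <- node_id(e$contig2[k], e$end2[k])
      if (n1 %in% used_end || n2 %in% used_end) {
        reason[k] <- "end_in_use"
      } else if (find(e$contig1[k]) == find(e$contig2[k])) {
        reason[k] <- "would_close_cycle"
      } else {
        acc[k] <- TRUE
        used_end <- c(used_end, n1, n2)
        parent[find(e$contig1[k])] <- find(e$contig2[k])
      }
    }
    accepted <- cbind(e[acc, , drop = FALSE],
                      gap_median = gap_med[acc], gap_mad = gap_mad[acc])
    conflicts <- cbind(e[!acc, c("contig1", "end1", "contig2", "end2", "support")],
                       reason = reason[!acc])
  }

  # adjacency: contig end -> (other contig, other end, edge row)
  adj <- list()
  if (!is.null(accepted) && nrow(accepted) > 0) {
    for (k in seq_len(nrow(accepted))) {
      adj[[node_id(accepted$contig1[k], accepted$end1[k])]] <-
        list(contig = accepted$contig2[k], end = accepted$end2[k], edge = k)
      adj[[node_id(accepted$contig2[k], accepted$end2[k])]] <-
        list(contig = accepted$contig1[k], end = accepted$end1[k], edge = k)
    }
  }
  other_end <- function(end) if (end == "tail") "head" else "tail"
  deg <- function(contig) {
    sum(!is.null(adj[[node_id(contig, "head")]]),
        !is.null(adj[[node_id(contig, "tail")]]))
  }
  contigs <- names(graph$contigs)
  visited <- stats::setNames(rep(FALSE, length(contigs)), contigs)
  paths <- list(); joins <- list(); sc <- 0L
  terminals <- sort(contigs[vapply(contigs, deg, numeric(1)) <= 1])
  for (start in terminals) {
    if (visited[[start]]) next
    sc <- sc + 1L
    scid <- sprintf("scaffold%04d", sc)
    # free end of the start contig (deterministic preference: head)
    cur <- start
    ein <- if (is.null(adj[[node_id(start, "head")]])) "head" else "tail"
    idx <- 0L
    gap_before <- NA_real_
    repeat {
      visited[[cur]] <- TRUE
      idx <- idx + 1L
      exit <- other_end(ein)
      paths[[length(paths) + 1L]] <- data.frame(
        scaffold = scid, idx = idx, contig = cur,
        orientation = if (exit == "tail") "+" else "-",
        gap_before = gap_before, stringsAsFactors = FALSE)
      nxt <- adj[[node_id(cur, exit)]]
      if (is.null(nxt) || visited[[nxt$contig]]) break
      med <- accepted$gap_median[nxt$edge]
      gap_before <- if (med <= 0) 10 else round(med)
      joins[[length(joins) + 1L]] <- data.frame(
        left_contig = cur, right_contig = nxt$contig,
        support = accepted$support[nxt$edge], gap_median = med,
        gap_est = gap_before, overlap_candidate = med <= -50,
        stringsAsFactors = FALSE)
      cur <- nxt$contig
      ein <- nxt$end
    }
  }
  list(paths = do.call(rbind, paths),
       joins = if (length(joins)) do.call(rbind, joins) else
         data.frame(left_contig = character(0), right_contig = character(0),
                    support = integer(0), gap_median = numeric(0),
                    gap_est = numeric(0), overlap_candidate = logical(0)),
       conflicts = conflicts)
}

#' Build scaffold sequences from linearized paths
#'
#' Concatenates oriented contig sequences with `N` runs of the estimated
#' gap sizes.
#'
#' @param linearized Result of [linearize_scaffolds()].
#' @param sequences Named character vector of contig sequences.
#' @return Named character vector of scaffold sequences.
#' @export
scaffold_sequences <- function(linearized, sequences) {
  p <- linearized$paths
  out <- character(0)
  for (scid in unique(p$scaffold)) {
    q <- p[p$scaffold == scid, , drop = FALSE]
    q <- q[order(q$idx), , drop = FALSE]
    parts <- character(0)
    for (i in seq_len(nrow(q))) {
      s <- sequences[[q$contig[i]]]
      if (q$orientation[i] == "-") s <- revcomp(s)
      if (i > 1) parts <- c(parts, strrep("N", max(q$gap_before[i], 0)))
      parts <- c(parts, s)
    }
    out[scid] <- paste(parts, collapse = "")
  }
  out
}
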