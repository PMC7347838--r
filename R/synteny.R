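# Synteny-block chaining, chromosome anchoring, collinearity verification,
# rearrangement counting and breakpoint positional profiling.

#' Chain whole-genome alignments into synteny blocks
#'
#' Alignments are filtered by mapping quality, sorted by query position,
#' and greedily merged into a block while they stay on the same target
#' sequence and strand, both the query gap and the (strand-aware) target
#' gap between consecutive members are at most `max_gap`, and the signed
#' target order is consistent (monotone along the strand; small overlaps
#' up to 100 bp are tolerated). Blocks whose query span is below
#' `min_block` are discarded. The result is deterministic and invariant
#' to the input row order.
#'
#' @param alignments Alignment table between exactly two assemblies
#'   (query = the assembly to anchor, target = the reference).
#' @param max_gap Maximum query/target gap inside a block (bp).
#' @param min_block Minimum query span of a reported block (bp).
#' @param min_mapq Minimum mapping quality of member alignments.
#' @return data.frame of blocks: `qname, qstart, qend, tname, tstart,
#'   tend, strand, aligned` (summed residue matches), `n_aln`.
#' @export
chain_synteny_blocks <- function(alignments, max_gap = 100000,
                                 min_block = 10000, min_mapq = 30) {
  a <- alignments[alignments$mapq >= min_mapq, , drop = FALSE]
  a <- a[order(a$qname, a$qstart, a$qend, a$tname, a$tstart), , drop = FALSE]
  blocks <- list()
  flush <- function(ch) {
    if (is.null(ch)) return()
    blocks[[length(blocks) + 1L]] <<- data.frame(
      qname = ch$qname, qstart = ch$qstart, qend = ch$qend,
      tname = ch$tname, tstart = ch$tstart, tend = ch$tend,
      strand = ch$strand, aligned = ch$aligned, n_aln = ch$n,
      stringsAsFactors = FALSE)
  }
  ch <- NULL
  tol <- 100 # tolerated coordinate overlap between members
  for (i in seq_len(nrow(a))) {
    r <- a[i, ]
    extend <- FALSE
    if (!is.null(ch) && r$qname == ch$qname && r$tname == ch$tname &&
        r$strand == ch$strand) {
      qgap <- r$qstart - ch$qend
      tgap <- if (r$strand == "+") r$tstart - ch$tend else ch$t_lead - r$tend
      extend <- qgap <= max_gap && qgap >= -tol &&
        tgap <= max_gap && tgap >= -tol
    }
    if (extend) {
      ch$qend <- max(ch$qend, r$qend)
      ch$tstart <- min(ch$tstart, r$tstart)
      ch$tend <- max(ch$tend, r$tend)
      ch$t_lead <- if (r$strand == "+") max(ch$t_lead, r$tend) else
        min(ch$t_lead, r$tstart)
      ch$aligned <- ch$aligned + r$nmatch
      ch$n <- ch$n + 1L
    } else {
      flush(ch)
      ch <- list(qname = r$qname, qstart = r$qstart, qend = r$qend,
                 tname = r$tname, tstart = r$tstart, tend = r$tend,
                 strand = r$strand,
                 t_lead = if (r$strand == "+") r$tend else r$tstart,
                 aligned = r$nmatch, n = 1L)
    }
  }
  flush(ch)
  out <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(qname = character(0), qstart = numeric(0), qend = numeric(0),
               tname = character(0), tstart = numeric(0), tend = numeric(0),
               strand = character(0), aligned = numeric(0), n_aln = integer(0),
               stringsAsFactors = FALSE)
  out <- out[out$qend - out$qstart >= min_block, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Anchor scaffolds to reference chromosomes by majority synteny
#'
#' Each scaffold is assigned to the reference chromosome holding a strict
#' majority (> 50%) of its block-aligned bases; ties and blockless
#' scaffolds are left unplaced. Anchored scaffolds are ordered along each
#' chromosome by the median target midpoint of their blocks and oriented
#' by the majority (aligned-base weighted) block orientation.
#'
#' @param blocks Synteny blocks from [chain_synteny_blocks()] (query =
#'   scaffolds, target = reference chromosomes).
#' @param scaffold_lengths Named vector of scaffold lengths (bp).
#' @param gap_len N-gap length between consecutive placed scaffolds.
#' @return List:
#'   * `assembly`: an `agp` chromosome assembly;
#'   * `placements`: data.frame `scaffold, chrom, position, orientation`;
#'   * `anchored_fraction`: anchored scaffold bases / total bases;
#'   * `unplaced`: character vector of unplaced scaffold ids.
#' @export
anchor_scaffolds <- function(blocks, scaffold_lengths, gap_len = 100) {
  place <- list()
  for (sc in names(scaffold_lengths)) {
    b <- blocks[blocks$qname == sc, , drop = FALSE]
    if (nrow(b) == 0) next
    by_t <- tapply(b$aligned, b$tname, sum)
    if (max(by_t) <= sum(by_t) / 2) next # no strict majority
    chrom <- names(by_t)[which.max(by_t)]
    bb <- b[b$tname == chrom, , drop = FALSE]
    pos <- stats::median((bb$tstart + bb$tend) / 2)
    by_s <- tapply(bb$aligned, bb$strand, sum)
    orient <- names(by_s)[which.max(by_s)]
    place[[length(place) + 1L]] <- data.frame(
      scaffold = sc, chrom = chrom, position = pos, orientation = orient,
      stringsAsFactors = FALSE)
  }
  placements <- if (length(place)) do.call(rbind, place) else
    data.frame(scaffold = character(0), chrom = character(0),
               position = numeric(0), orientation = character(0),
               stringsAsFactors = FALSE)
  placements <- placements[order(placements$chrom, placements$position), ,
                           drop = FALSE]
  rownames(placements) <- NULL
  unplaced <- setdiff(names(scaffold_lengths), placements$scaffold)
  anchored_fraction <- sum(scaffold_lengths[placements$scaffold]) /
    sum(scaffold_lengths)
  rows <- list()
  for (ch in unique(placements$chrom)) {
    p <- placements[placements$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(p))) {
      if (i > 1) {
        rows[[length(rows) + 1L]] <- data.frame(
          object = ch, type = "N", id = NA_character_, length = gap_len,
          orientation = NA_character_, linkage_evidence = "align_genus",
          stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        object = ch, type = "W", id = p$scaffold[i],
        length = unname(scaffold_lengths[p$scaffold[i]]),
        orientation = p$orientation[i], linkage_evidence = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  assembly <- if (length(rows)) agp_assembly(do.call(rbind, rows)) else NULL
  list(assembly = assembly, placements = placements,
       anchored_fraction = anchored_fraction, unplaced = unplaced)
}

#' Verify assembly junctions by collinearity with evidence assemblies
#'
#' A junction is `verified` when at least one evidence block set (blocks
#' of the assembly under test aligned to an alternative assembly or a
#' related species genome) spans both its flanks: either a single block
#' covering `pos +- min_flank`, or two blocks on the same target sequence,
#' same orientation, adjacent and order-consistent with a query gap at
#' most `max_gap`, together covering both flanks. Junctions verified by
#' no evidence set are `unverified` and can be fed to
#' [enumerate_junctions()] as breakpoints. Adding evidence can only turn
#' verdicts from unverified to verified.
#'
#' @param junctions data.frame with `seq_id`, `pos`.
#' @param evidence List of synteny-block data.frames (each from
#'   [chain_synteny_blocks()] with the assembly under test as query).
#' @param min_flank Flank (bp) that must be covered on each side.
#' @param max_gap Maximum query gap between the two spanning blocks (bp).
#' @return data.frame: `seq_id`, `pos`, `verdict` (`verified`/`unverified`).
#' @export
verify_collinearity <- function(junctions, evidence, min_flank = 100,
                                max_gap = 100000) {
  stopifnot(is.list(evidence), length(evidence) >= 1)
  ok_one <- function(b, pos) {
    any(b$qstart <= pos - min_flank & b$qend >= pos + min_flank)
  }
  ok_two <- function(b, pos) {
    b <- b[order(b$qstart), , drop = FALSE]
    if (nrow(b) < 2) return(FALSE)
    for (i in seq_len(nrow(b) - 1)) {
      b1 <- b[i, ]; b2 <- b[i + 1, ]
      if (b1$tname != b2$tname || b1$strand != b2$strand) next
      if (b2$qstart - b1$qend > max_gap) next
      if (!(b1$qstart <= pos - min_flank && b2$qend >= pos + min_flank)) next
      if (!(b1$qend <= pos && pos <= b2$qstart)) next
      torder_ok <- if (b1$strand == "+") b2$tstart >= b1$tend - 100 &&
        b2$tstart - b1$tend <= max_gap else
          b1$tstart >= b2$tend - 100 && b1$tstart - b2$tend <= max_gap
      if (torder_ok) return(TRUE)
    }
    FALSE
  }
  verdict <- vapply(seq_len(nrow(junctions)), function(i) {
    id <- junctions$seq_id[i]; pos <- junctions$pos[i]
    for (ev in evidence) {
      b <- ev[ev$qname == id, , drop = FALSE]
      if (nrow(b) == 0) next
      if (ok_one(b, pos) || ok_two(b, pos)) return("verified")
    }
    "unverified"
  }, character(1))
  data.frame(seq_id = junctions$seq_id, pos = junctions$pos,
             verdict = verdict, stringsAsFactors = FALSE)
}

# Collinear-backbone decomposition of one query chromosome's block
# sequence. Returns indices of a maximum-cardinality collinear chain
# (same strand, monotone target positions) that, among all maximum
# chains, minimizes the number of maximal complement runs. O(n^2) DP.
backbone_chain <- function(tpos, strand) {
  n <- length(tpos)
  best <- NULL
  for (orient in c("+", "-")) {
    ok <- strand == orient
    if (!any(ok)) next
    cmp <- if (orient == "+") function(a, b) a < b else function(a, b) a > b
    len <- rep(-Inf, n); gaps <- rep(Inf, n); prev <- rep(NA_integer_, n)
    for (i in which(ok)) {
      len[i] <- 1; gaps[i] <- as.integer(i > 1); prev[i] <- NA
      for (j in seq_len(i - 1)) {
        if (!ok[j] || len[j] < 0 || !cmp(tpos[j], tpos[i])) next
        cl <- len[j] + 1
        cg <- gaps[j] + as.integer(i > j + 1)
        if (cl > len[i] || (cl == len[i] && cg < gaps[i])) {
          len[i] <- cl; gaps[i] <- cg; prev[i] <- j
        }
      }
    }
    ends <- which(is.finite(gaps))
    if (length(ends) == 0) next
    tot <- gaps[ends] + as.integer(ends < n)
    pick <- ends[order(-len[ends], tot)][1]
    cand <- list(len = len[pick], runs = tot[order(-len[ends], tot)][1],
                 chain = {
                   ix <- integer(0); i <- pick
                   while (!is.na(i)) { ix <- c(i, ix); i <- prev[i] }
                   ix
                 })
    if (is.null(best) || cand$len > best$len ||
        (cand$len == best$len && cand$runs < best$runs)) best <- cand
  }
  best
}

#' Count chromosomal rearrangements between two assemblies
#'
#' Per query chromosome, blocks are ordered by query position. Blocks
#' aligning to a target chromosome other than the query chromosome's
#' majority ("home") chromosome form inter-chromosomal events, one per
#' maximal run. The remaining blocks are decomposed into a
#' maximum-cardinality collinear backbone (consistent strand, monotone
#' target positions; ties broken toward fewest disruptions) plus maximal
#' runs of displaced blocks; each run is one intra-chromosomal event,
#' classified as an inversion when every block in the run is oriented
#' against the backbone, otherwise as a transposition. Comparing an
#' assembly with itself yields zero events.
#'
#' @param blocks Synteny blocks between two chromosome-scale assemblies.
#' @return List of class `rearrangement_report`:
#'   * `intra`, `inter`: event counts;
#'   * `events`: data.frame `qname, kind, tname, q_from, q_to, n_blocks`;
#'   * `breakpoints`: data.frame `chrom, pos` (target-side coordinates,
#'     two per event);
#'   * `n_breakpoints`: raw breakpoint count.
#' @export
count_rearrangements <- function(blocks) {
  events <- list(); bps <- list()
  for (q in unique(blocks$qname)) {
    b <- blocks[blocks$qname == q, , drop = FALSE]
    b <- b[order(b$qstart), , drop = FALSE]
    by_t <- tapply(b$aligned, b$tname, sum)
    home <- names(by_t)[which.max(by_t)]
    off <- b$tname != home
    # inter events: maximal runs of off-home blocks
    r <- rle(off)
    pos <- cumsum(c(1, r$lengths))
    for (k in which(r$values)) {
      ix <- seq(pos[k], pos[k + 1] - 1)
      events[[length(events) + 1L]] <- data.frame(
        qname = q, kind = "translocation", tname = b$tname[ix[1]],
        q_from = b$qstart[ix[1]], q_to = b$qend[ix[length(ix)]],
        n_blocks = length(ix), stringsAsFactors = FALSE)
      bps[[length(bps) + 1L]] <- data.frame(
        chrom = b$tname[ix[1]],
        pos = c(min(b$tstart[ix]), max(b$tend[ix])), stringsAsFactors = FALSE)
    }
    h <- b[!off, , drop = FALSE]
    if (nrow(h) == 0) next
    bk <- backbone_chain((h$tstart + h$tend) / 2, h$strand)
    if (is.null(bk)) next
    in_bk <- seq_len(nrow(h)) %in% bk$chain
    bk_strand <- h$strand[bk$chain[1]]
    r <- rle(!in_bk)
    pos <- cumsum(c(1, r$lengths))
    for (k in which(r$values)) {
      ix <- seq(pos[k], pos[k + 1] - 1)
      kind <- if (all(h$strand[ix] != bk_strand)) "inversion" else "transposition"
      events[[length(events) + 1L]] <- data.frame(
        qname = q, kind = kind, tname = home,
        q_from = h$qstart[ix[1]], q_to = h$qend[ix[length(ix)]],
        n_blocks = length(ix), stringsAsFactors = FALSE)
      bps[[length(bps) + 1L]] <- data.frame(
        chrom = home, pos = c(min(h$tstart[ix]), max(h$tend[ix])),
        stringsAsFactors = FALSE)
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(qname = character(0), kind = character(0), tname = character(0),
               q_from = numeric(0), q_to = numeric(0), n_blocks = integer(0),
               stringsAsFactors = FALSE)
  bp <- if (length(bps)) do.call(rbind, bps) else
    data.frame(chrom = character(0), pos = numeric(0), stringsAsFactors = FALSE)
  structure(list(intra = sum(ev$kind %in% c("inversion", "transposition")),
                 inter = sum(ev$kind == "translocation"),
                 events = ev, breakpoints = bp,
                 n_breakpoints = nrow(bp)),
            class = "rearrangement_report")
}

#' Positional profile of rearrangement breakpoints along chromosomes
#'
#' Maps every breakpoint to its relative distance to the nearest
#' chromosome end, `min(d_start, d_end) / (L/2)` in `[0, 1]` (1 = the
#' chromosome midpoint), and bins the values into a normalized histogram.
#' An enrichment of mass in the low bins indicates rearrangements
#' concentrating toward chromosome ends.
#'
#' @param report A `rearrangement_report` (or a data.frame with `chrom`,
#'   `pos`).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n_bins Number of histogram bins (>= 2).
#' @return data.frame: `bin_lo`, `bin_hi`, `count`, `freq` (sums to 1);
#'   zero rows if there are no breakpoints.
#' @export
breakpoint_position_profile <- function(report, chrom_lengths, n_bins = 10) {
  stopifnot(n_bins >= 2)
  bp <- if (inherits(report, "rearrangement_report")) report$breakpoints else report
  if (nrow(bp) == 0) {
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      count = numeric(0), freq = numeric(0)))
  }
  fail_if(any(!bp$chrom %in% names(chrom_lengths)),
          "breakpoint on unknown chromosome: %s",
          bp$chrom[which(!bp$chrom %in% names(chrom_lengths))[1]])
  L <- chrom_lengths[bp$chrom]
  fail_if(any(bp$pos < 0 | bp$pos > L), "breakpoint outside chromosome")
  rel <- pmin(bp$pos, L - bp$pos) / (L / 2)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  idx <- pmin(findInterval(rel, breaks, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             count = counts, freq = counts / sum(counts))
}
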