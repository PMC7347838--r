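# Fragmentation and structural-event planting.
#
# The derived assembly is described by a *layout*: per derived sequence, an
# ordered set of rows, each either a source segment (chrom interval +
# strand) or a gap of Ns. Gap rows carry `bridged = TRUE` when the two
# flanking segments are genome-contiguous on the same strand (a true
# scaffold join a long read can span) and `bridged = FALSE` for chimeric
# (fusion) joins no read from the true genome can span.

seq_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

fragment_genome <- function(lens, target_n50, min_frag) {
  frag <- data.frame(chrom = names(lens), start = 0, end = unname(lens),
                     stringsAsFactors = FALSE)
  repeat {
    w <- frag$end - frag$start
    if (seq_n50(w) <= target_n50) break
    cand <- which(w >= 2 * min_frag)
    if (length(cand) == 0) break
    i <- if (length(cand) == 1) cand else sample(cand, 1, prob = w[cand])
    cut <- frag$start[i] + min_frag +
      floor(stats::runif(1) * (w[i] - 2 * min_frag))
    frag <- rbind(frag[-i, , drop = FALSE],
                  data.frame(chrom = frag$chrom[i], start = frag$start[i],
                             end = cut, stringsAsFactors = FALSE),
                  data.frame(chrom = frag$chrom[i], start = cut,
                             end = frag$end[i], stringsAsFactors = FALSE))
  }
  frag <- frag[order(frag$chrom, frag$start), , drop = FALSE]
  rownames(frag) <- NULL
  frag
}

frag_seq <- function(genome, chrom, start, end) {
  substring(genome[[chrom]], start + 1, end)
}

#' Plant misassemblies into a fragmented genome
#'
#' Fragments the genome to a target N50 (uniform breakpoints, as a simple
#' seedable model of contig structure), then plants structural defects with
#' recorded truth:
#'
#' * **fusion** — two fragments from *different* chromosomes concatenated
#'   across an N gap (a chimeric join; no true read spans it);
#' * **inversion** — an internal interval of a fragment reverse-complemented
#'   in place (two breakpoints);
#' * **translocation** — an internal interval cut from a donor fragment and
#'   inserted into an acceptor fragment from another chromosome;
#' * **true join** (`n_true_joins`) — two genome-adjacent fragments of the
#'   same chromosome rejoined across an N gap. These emulate correct
#'   scaffold joins: spanning reads exist, so junction validation has
#'   support-positive junctions to leave intact.
#'
#' With all event counts zero the result is a plain fragmentation (each
#' fragment its own sequence, no gaps).
#'
#' @param genome Named character vector of chromosome sequences.
#' @param n_fusion,n_inversion,n_translocation Event counts.
#' @param fragment_n50_target Fragment N50 to fragment down to (bp).
#' @param n_true_joins Number of genome-contiguous rejoined pairs.
#' @param gap_len N-gap length inserted at fusion and true-join junctions.
#' @param min_frag Minimum fragment length produced by fragmentation (bp).
#' @param seed Integer seed.
#' @return List with:
#'   * `sequences`: named character vector (the derived assembly);
#'   * `layout`: data.frame (`seq_id, dstart, dend, type, src, sstart,
#'     send, strand, bridged`), derived coordinates 0-based half-open;
#'   * `events`: data.frame (`event_id, kind, seq_id`);
#'   * `breakpoints`: data.frame (`event_id, kind, seq_id, pos`), one row
#'     per junction/breakpoint coordinate on the derived assembly.
#' @export
plant_misassemblies <- function(genome, n_fusion = 0, n_inversion = 0,
                                n_translocation = 0, fragment_n50_target,
                                n_true_joins = 0, gap_len = 100,
                                min_frag = 1000, seed = 1) {
  stopifnot(n_fusion >= 0, n_inversion >= 0, n_translocation >= 0,
            n_true_joins >= 0)
  lens <- seq_lengths(genome)
  with_seed(seed, {
    frag <- fragment_genome(lens, fragment_n50_target, min_frag)
    nfr <- nrow(frag)
    used <- rep(FALSE, nfr)
    flen <- frag$end - frag$start
    margin <- 500

    layout <- list()
    events <- list()
    bps <- list()
    seqs <- list()
    eid <- 0L
    sid <- 0L
    new_seq_id <- function() sprintf("scf%05d", sid)

    add_event <- function(kind, seq_id, positions) {
      eid <<- eid + 1L
      events[[length(events) + 1L]] <<-
        data.frame(event_id = eid, kind = kind, seq_id = seq_id,
                   stringsAsFactors = FALSE)
      if (length(positions)) {
        bps[[length(bps) + 1L]] <<-
          data.frame(event_id = eid, kind = kind, seq_id = seq_id,
                     pos = positions, stringsAsFactors = FALSE)
      }
    }
    seg_row <- function(seq_id, dstart, dend, chrom, sstart, send, strand) {
      data.frame(seq_id = seq_id, dstart = dstart, dend = dend,
                 type = "segment", src = chrom, sstart = sstart, send = send,
                 strand = strand, bridged = NA, stringsAsFactors = FALSE)
    }
    gap_row <- function(seq_id, dstart, gap_len, bridged) {
      data.frame(seq_id = seq_id, dstart = dstart, dend = dstart + gap_len,
                 type = "gap", src = NA_character_, sstart = NA_real_,
                 send = NA_real_, strand = NA_character_, bridged = bridged,
                 stringsAsFactors = FALSE)
    }

    # --- true joins: genome-adjacent same-chromosome fragment pairs -----
    for (k in seq_len(n_true_joins)) {
      adj <- which(!used[-nfr] & !used[-1] &
                     frag$chrom[-nfr] == frag$chrom[-1] &
                     frag$end[-nfr] == frag$start[-1])
      fail_if(length(adj) == 0,
              "genome too fragmented/small for %d true joins", n_true_joins)
      i <- if (length(adj) == 1) adj else sample(adj, 1)
      used[c(i, i + 1L)] <- TRUE
      sid <- sid + 1L; id <- new_seq_id()
      la <- flen[i]
      layout[[length(layout) + 1L]] <- rbind(
        seg_row(id, 0, la, frag$chrom[i], frag$start[i], frag$end[i], "+"),
        gap_row(id, la, gap_len, TRUE),
        seg_row(id, la + gap_len, la + gap_len + flen[i + 1L],
                frag$chrom[i + 1L], frag$start[i + 1L], frag$end[i + 1L], "+"))
      seqs[[id]] <- paste0(
        frag_seq(genome, frag$chrom[i], frag$start[i], frag$end[i]),
        strrep("N", gap_len),
        frag_seq(genome, frag$chrom[i + 1L], frag$start[i + 1L], frag$end[i + 1L]))
      add_event("join", id, c(la, la + gap_len))
    }

    # --- fusions: cross-chromosome chimeric joins -----------------------
    for (k in seq_len(n_fusion)) {
      free <- which(!used)
      fail_if(length(free) < 2, "genome too small for %d fusions", n_fusion)
      a <- if (length(free) == 1) free else sample(free, 1)
      partners <- which(!used & frag$chrom != frag$chrom[a])
      fail_if(length(partners) == 0,
              "need fragments from >= 2 chromosomes for fusions")
      b <- if (length(partners) == 1) partners else sample(partners, 1)
      used[c(a, b)] <- TRUE
      sid <- sid + 1L; id <- new_seq_id()
      la <- flen[a]
      layout[[length(layout) + 1L]] <- rbind(
        seg_row(id, 0, la, frag$chrom[a], frag$start[a], frag$end[a], "+"),
        gap_row(id, la, gap_len, FALSE),
        seg_row(id, la + gap_len, la + gap_len + flen[b],
                frag$chrom[b], frag$start[b], frag$end[b], "+"))
      seqs[[id]] <- paste0(
        frag_seq(genome, frag$chrom[a], frag$start[a], frag$end[a]),
        strrep("N", gap_len),
        frag_seq(genome, frag$chrom[b], frag$start[b], frag$end[b]))
      add_event("fusion", id, c(la, la + gap_len))
    }

    # --- inversions -----------------------------------------------------
    min_inv <- 500
    for (k in seq_len(n_inversion)) {
      cand <- which(!used & flen >= 2 * margin + min_inv)
      fail_if(length(cand) == 0, "no fragment large enough for inversion %d", k)
      i <- if (length(cand) == 1) cand else sample(cand, 1)
      used[i] <- TRUE
      L <- flen[i]
      a <- margin + floor(stats::runif(1) * (L - 2 * margin - min_inv))
      b <- a + min_inv + floor(stats::runif(1) * (L - margin - a - min_inv))
      sid <- sid + 1L; id <- new_seq_id()
      fs <- frag$start[i]; ch <- frag$chrom[i]
      layout[[length(layout) + 1L]] <- rbind(
        seg_row(id, 0, a, ch, fs, fs + a, "+"),
        seg_row(id, a, b, ch, fs + a, fs + b, "-"),
        seg_row(id, b, L, ch, fs + b, fs + L, "+"))
      seqs[[id]] <- paste0(
        frag_seq(genome, ch, fs, fs + a),
        revcomp(frag_seq(genome, ch, fs + a, fs + b)),
        frag_seq(genome, ch, fs + b, fs + L))
      add_event("inversion", id, c(a, b))
    }

    # --- translocations -------------------------------------------------
    for (k in seq_len(n_translocation)) {
      donors <- which(!used & flen >= 2 * margin + 2000)
      fail_if(length(donors) == 0, "no donor fragment for translocation %d", k)
      d <- if (length(donors) == 1) donors else sample(donors, 1)
      acceptors <- which(!used & frag$chrom != frag$chrom[d] &
                           flen >= 2 * margin)
      fail_if(length(acceptors) == 0, "no acceptor fragment for translocation %d", k)
      r <- if (length(acceptors) == 1) acceptors else sample(acceptors, 1)
      used[c(d, r)] <- TRUE
      Ld <- flen[d]
      seg_len <- 500 + floor(stats::runif(1) * min(1500, Ld - 2 * margin - 500))
      a <- margin + floor(stats::runif(1) * (Ld - 2 * margin - seg_len))
      b <- a + seg_len
      ds <- frag$start[d]; dch <- frag$chrom[d]
      Lr <- flen[r]
      p <- margin + floor(stats::runif(1) * (Lr - 2 * margin))
      rs <- frag$start[r]; rch <- frag$chrom[r]
      # donor minus the excised interval
      sid <- sid + 1L; id1 <- new_seq_id()
      layout[[length(layout) + 1L]] <- rbind(
        seg_row(id1, 0, a, dch, ds, ds + a, "+"),
        seg_row(id1, a, Ld - seg_len, dch, ds + b, ds + Ld, "+"))
      seqs[[id1]] <- paste0(frag_seq(genome, dch, ds, ds + a),
                            frag_seq(genome, dch, ds + b, ds + Ld))
      add_event("translocation_excision", id1, a)
      # acceptor with the interval inserted at p
      sid <- sid + 1L; id2 <- new_seq_id()
      layout[[length(layout) + 1L]] <- rbind(
        seg_row(id2, 0, p, rch, rs, rs + p, "+"),
        seg_row(id2, p, p + seg_len, dch, ds + a, ds + b, "+"),
        seg_row(id2, p + seg_len, Lr + seg_len, rch, rs + p, rs + Lr, "+"))
      seqs[[id2]] <- paste0(frag_seq(genome, rch, rs, rs + p),
                            frag_seq(genome, dch, ds + a, ds + b),
                            frag_seq(genome, rch, rs + p, rs + Lr))
      add_event("translocation", id2, c(p, p + seg_len))
    }

    # --- remaining fragments pass through unchanged ---------------------
    for (i in which(!used)) {
      sid <- sid + 1L; id <- new_seq_id()
      layout[[length(layout) + 1L]] <-
        seg_row(id, 0, flen[i], frag$chrom[i], frag$start[i], frag$end[i], "+")
      seqs[[id]] <- frag_seq(genome, frag$chrom[i], frag$start[i], frag$end[i])
    }

    empty_events <- data.frame(event_id = integer(0), kind = character(0),
                               seq_id = character(0), stringsAsFactors = FALSE)
    empty_bps <- data.frame(event_id = integer(0), kind = character(0),
                            seq_id = character(0), pos = numeric(0),
                            stringsAsFactors = FALSE)
    list(sequences = unlist(seqs),
         layout = {x <- do.call(rbind, layout); rownames(x) <- NULL; x},
         events = if (length(events)) do.call(rbind, events) else empty_events,
         breakpoints = if (length(bps)) do.call(rbind, bps) else empty_bps)
  })
}

#' Project genome-truth alignments onto a derived assembly
#'
#' Deterministically maps alignments given in true-genome coordinates (for
#' example the truth PAF of [simulate_long_reads()]) onto the derived
#' assembly described by a misassembly layout. Each alignment is
#' intersected with the layout's source segments; pieces falling in
#' adjacent segments separated by a *bridged* gap (genome-contiguous true
#' join) are merged into a single record spanning the gap, emulating how a
#' true read aligns across a correct scaffold gap. Pieces on either side of
#' a chimeric (fusion) junction or an inversion/translocation breakpoint
#' stay separate records clipped at the junction.
#'
#' @param aln Alignment table in genome coordinates (`tname` = chromosome).
#' @param layout Layout data.frame from [plant_misassemblies()].
#' @param min_len Minimum piece length to report after merging (bp).
#' @return Alignment table (see [paf_records()]) in derived-assembly
#'   coordinates.
#' @export
lift_alignments <- function(aln, layout, min_len = 50) {
  seg <- layout[layout$type == "segment", , drop = FALSE]
  dlen <- vapply(split(layout$dend, layout$seq_id), max, numeric(1))
  gaps <- layout[layout$type == "gap" & layout$bridged %in% TRUE, , drop = FALSE]
  bridge_keys <- paste(gaps$seq_id, gaps$dstart, gaps$dend)

  pieces <- list()
  for (ch in unique(aln$tname)) {
    a <- aln[aln$tname == ch, , drop = FALSE]
    s <- seg[seg$src == ch, , drop = FALSE]
    if (nrow(s) == 0 || nrow(a) == 0) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = a$tstart + 1, end = a$tend),
      IRanges::IRanges(start = s$sstart + 1, end = s$send))
    if (length(ov) == 0) next
    ai <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    ov_s <- pmax(a$tstart[ai], s$sstart[si])
    ov_e <- pmin(a$tend[ai], s$send[si])
    plus_seg <- s$strand[si] == "+"
    t0 <- ifelse(plus_seg, s$dstart[si] + (ov_s - s$sstart[si]),
                 s$dstart[si] + (s$send[si] - ov_e))
    t1 <- ifelse(plus_seg, s$dstart[si] + (ov_e - s$sstart[si]),
                 s$dstart[si] + (s$send[si] - ov_s))
    plus_read <- a$strand[ai] == "+"
    q0 <- ifelse(plus_read, ov_s - a$tstart[ai], a$tend[ai] - ov_e)
    q1 <- q0 + (ov_e - ov_s)
    acc <- a$nmatch[ai] / a$blocklen[ai] # read accuracy carried over
    pieces[[length(pieces) + 1L]] <- data.frame(
      qname = a$qname[ai], qlen = a$qlen[ai], qstart = q0, qend = q1,
      strand = ifelse(plus_read == plus_seg, "+", "-"),
      tname = s$seq_id[si], tlen = unname(dlen[s$seq_id[si]]),
      tstart = t0, tend = t1,
      nmatch = round((ov_e - ov_s) * acc), blocklen = t1 - t0,
      mapq = a$mapq[ai], stringsAsFactors = FALSE)
  }
  if (length(pieces) == 0) {
    return(paf_records(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = 12)), paf_cols)))
  }
  p <- do.call(rbind, pieces)
  p <- p[order(p$qname, p$tname, p$tstart), , drop = FALSE]

  # merge consecutive pieces of one read across bridged gaps
  n <- nrow(p)
  keep <- rep(TRUE, n)
  chain <- 1L
  if (n > 1) {
    for (i in 2:n) {
      same <- p$qname[i] == p$qname[chain] && p$tname[i] == p$tname[chain]
      if (same &&
          paste(p$tname[i], p$tend[chain], p$tstart[i]) %in% bridge_keys) {
        p$tend[chain] <- p$tend[i]
        p$qstart[chain] <- min(p$qstart[chain], p$qstart[i])
        p$qend[chain] <- max(p$qend[chain], p$qend[i])
        p$nmatch[chain] <- p$nmatch[chain] + p$nmatch[i]
        p$blocklen[chain] <- p$tend[chain] - p$tstart[chain]
        keep[i] <- FALSE
      } else {
        chain <- i
      }
    }
  }
  p <- p[keep & (p$tend - p$tstart) >= min_len, , drop = FALSE]
  paf_records(p)
}
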