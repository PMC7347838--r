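#' Simulate a chromosome-scale genome with telomeric termini
#'
#' Each chromosome starts with `(CCCTAA)` repeated `telomere_units` times
#' and ends with the reverse-complement array `(TTAGGG)` repeated the same
#' number of times, matching the vertebrate telomeric repeat as it appears
#' on the forward strand of an assembled chromosome. The interior is i.i.d.
#' nucleotides at the requested GC content.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Length of each chromosome (bp). Scalar or vector of
#'   length `n_chrom`.
#' @param telomere_units Number of 6-bp telomere units per terminus.
#' @param gc GC fraction of the interior, in (0, 1).
#' @param seed Integer seed; identical inputs give identical output.
#' @return Named character vector of chromosome sequences
#'   (`chr01`, `chr02`, ...).
#' @export
simulate_genome <- function(n_chrom, chrom_len, telomere_units = 10,
                            gc = 0.41, seed = 1) {
  stopifnot(n_chrom >= 1, telomere_units >= 0, gc > 0, gc < 1)
  chrom_len <- rep_len(chrom_len, n_chrom)
  fail_if(any(chrom_len < 2 * 6 * telomere_units),
          "chrom_len too short for %d telomere units per end", telomere_units)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  tel5 <- strrep("CCCTAA", telomere_units)
  tel3 <- strrep("TTAGGG", telomere_units)
  with_seed(seed, {
    seqs <- vapply(seq_len(n_chrom), function(i) {
      inner <- chrom_len[i] - 12 * telomere_units
      body <- paste(sample(names(probs), inner, replace = TRUE, prob = probs),
                    collapse = "")
      paste0(tel5, body, tel3)
    }, character(1))
    stats::setNames(seqs, sprintf("chr%02d", seq_len(n_chrom)))
  })
}

#' Simulate long reads with truth alignments
#'
#' Draws reads from the genome at a target fold-coverage: chromosomes are
#' chosen proportionally to length, read lengths are normal (truncated),
#' start positions uniform, strands fair. With `error_rate > 0`,
#' substitution errors are applied uniformly (no indels, so every truth
#' alignment is full-length and gap-free). The truth alignment of every
#' read is emitted as a PAF record with `mapq = 60`.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param coverage Target fold coverage (> 0); total read bases stop at the
#'   first read reaching `coverage * genome size`.
#' @param mean_len,len_sd Read length distribution (bp); lengths are
#'   truncated to `[200, shortest chromosome]`.
#' @param error_rate Per-base substitution rate in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with `reads` (named character vector) and `truth`
#'   (alignment table, see [paf_records()]).
#' @export
simulate_long_reads <- function(genome, coverage, mean_len = 10000,
                                len_sd = 1000, error_rate = 0, seed = 1) {
  stopifnot(coverage > 0, error_rate >= 0, error_rate < 1)
  lens <- seq_lengths(genome)
  fail_if(mean_len > max(lens), "mean_len exceeds the longest chromosome")
  gsize <- sum(lens)
  target <- coverage * gsize
  with_seed(seed, {
    # draw generously, then trim to the first read crossing the target
    n_guess <- ceiling(target / mean_len * 1.3) + 10
    rl <- pmin(pmax(round(stats::rnorm(n_guess, mean_len, len_sd)), 200), min(lens))
    keep <- which(cumsum(rl) >= target)[1]
    fail_if(is.na(keep), "internal: read draw underestimated coverage")
    rl <- rl[seq_len(keep)]
    chrom <- sample(names(lens), keep, replace = TRUE, prob = lens / gsize)
    start <- floor(stats::runif(keep) * (lens[chrom] - rl)) # 0-based
    strand <- sample(c("+", "-"), keep, replace = TRUE)
    ids <- sprintf("read%06d", seq_len(keep))
    reads <- substring(genome[chrom], start + 1, start + rl)
    rc <- strand == "-"
    reads[rc] <- revcomp(reads[rc])
    nerr <- integer(keep)
    if (error_rate > 0) {
      nerr <- stats::rbinom(keep, rl, error_rate)
      for (i in which(nerr > 0)) {
        pos <- sample.int(rl[i], nerr[i])
        s <- strsplit(reads[i], "", fixed = TRUE)[[1]]
        repl <- sample(c("A", "C", "G", "T"), nerr[i], replace = TRUE)
        same <- repl == s[pos]
        while (any(same)) { # force a true substitution
          repl[same] <- sample(c("A", "C", "G", "T"), sum(same), replace = TRUE)
          same <- repl == s[pos]
        }
        s[pos] <- repl
        reads[i] <- paste(s, collapse = "")
      }
    }
    truth <- paf_records(data.frame(
      qname = ids, qlen = rl, qstart = 0, qend = rl, strand = strand,
      tname = chrom, tlen = unname(lens[chrom]), tstart = unname(start),
      tend = unname(start + rl), nmatch = rl - nerr, blocklen = rl,
      mapq = 60, stringsAsFactors = FALSE))
    list(reads = stats::setNames(reads, ids), truth = truth)
  })
}

#' Specify an insert-size mixture for a gel-free mate-pair library
#'
#' @param weight Component weights (must sum to 1).
#' @param mean,sd Insert size mean and SD per component (bp).
#' @param orientation `"inward"` (paired-end contaminants) or `"outward"`
#'   (circularization-derived true mate pairs) per component.
#' @return data.frame of class `insert_mixture`.
#' @export
insert_mixture <- function(weight, mean, sd, orientation) {
  stopifnot(length(weight) == length(mean), length(mean) == length(sd),
            length(sd) == length(orientation))
  fail_if(abs(sum(weight) - 1) > 1e-9, "mixture weights must sum to 1")
  fail_if(any(weight < 0), "mixture weights must be >= 0")
  fail_if(any(mean <= 0), "insert means must be > 0")
  fail_if(any(!orientation %in% c("inward", "outward")),
          "orientation must be 'inward' or 'outward'")
  out <- data.frame(component = seq_along(weight), weight = weight,
                    mean = mean, sd = sd, orientation = orientation,
                    stringsAsFactors = FALSE)
  class(out) <- c("insert_mixture", "data.frame")
  out
}

#' Simulate a gel-free mate-pair library with truth labels
#'
#' Emulates a mate-pair preparation without physical size selection: each
#' pair is drawn from a mixture of inward-facing small-insert contaminants
#' and outward-facing large-insert true mate pairs. Fragments are placed
#' uniformly; the two reads sit at the fragment ends with the component's
#' orientation. Truth alignments (`mapq = 60`) and per-pair component
#' labels are returned for downstream classification accuracy checks.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param n_pairs Number of pairs.
#' @param spec An [insert_mixture()]; every component mean must exceed
#'   `2 * read_len`.
#' @param read_len Read length (bp).
#' @param seed Integer seed.
#' @return List with `pairs` (data.frame: `pair_id`, `component`,
#'   `orientation`, `insert`, `chrom`, `fstart`) and `truth` (alignment
#'   table, two rows per pair, query names `<pair_id>/1` and `<pair_id>/2`).
#' @export
simulate_gelfree_matepairs <- function(genome, n_pairs, spec, read_len = 100,
                                       seed = 1) {
  spec <- if (inherits(spec, "insert_mixture")) spec else
    insert_mixture(spec$weight, spec$mean, spec$sd, spec$orientation)
  fail_if(any(spec$mean <= 2 * read_len),
          "all component insert means must exceed 2 * read_len")
  lens <- seq_lengths(genome)
  if (n_pairs == 0) {
    empty <- paf_records(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = 12)), paf_cols))
    return(list(pairs = data.frame(pair_id = character(0), component = integer(0),
                                   orientation = character(0), insert = numeric(0),
                                   chrom = character(0), fstart = numeric(0)),
                truth = empty))
  }
  with_seed(seed, {
    comp <- sample(spec$component, n_pairs, replace = TRUE, prob = spec$weight)
    ins <- round(stats::rnorm(n_pairs, spec$mean[comp], spec$sd[comp]))
    ins <- pmax(ins, 2 * read_len + 1)
    ins <- pmin(ins, min(lens))
    chrom <- sample(names(lens), n_pairs, replace = TRUE, prob = lens / sum(lens))
    fstart <- floor(stats::runif(n_pairs) * (lens[chrom] - ins))
    orient <- spec$orientation[comp]
    ids <- sprintf("pair%06d", seq_len(n_pairs))
    # read 1 at the fragment start, read 2 at the fragment end;
    # inward: + / -  (reads point toward each other)
    # outward: - / + (reads point away, as after circularization)
    s1 <- ifelse(orient == "inward", "+", "-")
    s2 <- ifelse(orient == "inward", "-", "+")
    truth <- paf_records(data.frame(
      qname = c(paste0(ids, "/1"), paste0(ids, "/2")),
      qlen = read_len, qstart = 0, qend = read_len,
      strand = c(s1, s2),
      tname = c(chrom, chrom), tlen = unname(c(lens[chrom], lens[chrom])),
      tstart = unname(c(fstart, fstart + ins - read_len)),
      tend = unname(c(fstart + read_len, fstart + ins)),
      nmatch = read_len, blocklen = read_len, mapq = 60,
      stringsAsFactors = FALSE))
    list(pairs = data.frame(pair_id = ids, component = comp,
                            orientation = orient, insert = as.numeric(ins),
                            chrom = unname(chrom), fstart = unname(fstart),
                            stringsAsFactors = FALSE),
         truth = truth)
  })
}
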