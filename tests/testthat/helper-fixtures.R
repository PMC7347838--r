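# Shared fixture builders. Everything is generated in code at test time.

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# a perfectly collinear block list on one chromosome, optionally with
# inverted runs (strand flip + reversed within-run target order) and
# blocks moved to another chromosome
make_blocks <- function(n, qname = "q1", chrom = "chrA", block = 10000,
                        inv_runs = list(), move = integer(0)) {
  b <- data.frame(
    qname = qname,
    qstart = (0:(n - 1)) * block, qend = (0:(n - 1)) * block + block - 1000,
    tname = chrom,
    tstart = (0:(n - 1)) * block, tend = (0:(n - 1)) * block + block - 1000,
    strand = "+", aligned = block - 1000, n_aln = 1,
    stringsAsFactors = FALSE)
  for (run in inv_runs) {
    b$strand[run] <- "-"
    b$tstart[run] <- rev(b$tstart[run])
    b$tend[run] <- rev(b$tend[run])
  }
  if (length(move)) b$tname[move] <- "chrB"
  b
}

# alignment row helper
aln_row <- function(qname, tname, tstart, tend, mapq = 60, strand = "+",
                    qlen = NULL, tlen = 1e6, qstart = 0, qend = NULL) {
  len <- tend - tstart
  if (is.null(qlen)) qlen <- len
  if (is.null(qend)) qend <- qstart + len
  paf_records(data.frame(
    qname = qname, qlen = qlen, qstart = qstart, qend = qend,
    strand = strand, tname = tname, tlen = tlen, tstart = tstart,
    tend = tend, nmatch = len, blocklen = len, mapq = mapq,
    stringsAsFactors = FALSE))
}

# true genome-adjacency table implied by a fragmentation layout
true_adjacencies <- function(layout) {
  seg <- layout[layout$type == "segment", , drop = FALSE]
  seg <- seg[order(seg$src, seg$sstart), , drop = FALSE]
  ok <- seg$src[-nrow(seg)] == seg$src[-1] &
    seg$send[-nrow(seg)] == seg$sstart[-1]
  data.frame(left = seg$seq_id[-nrow(seg)][ok],
             right = seg$seq_id[-1][ok], stringsAsFactors = FALSE)
}

# adjacency pairs (with orientations) recovered from linearized paths
recovered_adjacencies <- function(paths) {
  out <- lapply(split(paths, paths$scaffold), function(q) {
    q <- q[order(q$idx), , drop = FALSE]
    if (nrow(q) < 2) return(NULL)
    data.frame(left = q$contig[-nrow(q)], right = q$contig[-1],
               left_or = q$orientation[-nrow(q)],
               right_or = q$orientation[-1], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# fraction of true adjacencies recovered with consistent orientation
adjacency_recall <- function(paths, layout) {
  truth <- true_adjacencies(layout)
  rec <- recovered_adjacencies(paths)
  if (is.null(rec)) return(0)
  key <- paste(truth$left, truth$right)
  ok <- (paste(rec$left, rec$right) %in% key &
           rec$left_or == "+" & rec$right_or == "+") |
    (paste(rec$right, rec$left) %in% key &
       rec$left_or == "-" & rec$right_or == "-")
  sum(ok) / nrow(truth)
}
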