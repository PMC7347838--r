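test_that("chaining merges collinear alignments within the gap budget", {
  two <- paf_records(data.frame(
    qname = "s1", qlen = 1e5, qstart = c(0, 14000), qend = c(9000, 20000),
    strand = "+", tname = "c1", tlen = 2e5, tstart = c(50000, 64000),
    tend = c(59000, 70000), nmatch = 6000, blocklen = 6000, mapq = 60,
    stringsAsFactors = FALSE))
  expect_equal(nrow(chain_synteny_blocks(two, max_gap = 10000, min_block = 1000)), 1)
  expect_equal(nrow(chain_synteny_blocks(two, max_gap = 1000, min_block = 1000)), 2)
  # mixed orientations never co-chain
  mixed <- two
  mixed$strand <- c("+", "-")
  expect_equal(nrow(chain_synteny_blocks(mixed, max_gap = 10000, min_block = 1000)), 2)
  # short blocks are discarded
  expect_equal(nrow(chain_synteny_blocks(two, max_gap = 1000, min_block = 50000)), 0)
  # deterministic and order-invariant
  b1 <- chain_synteny_blocks(two, 10000, 1000)
  b2 <- chain_synteny_blocks(two[2:1, ], 10000, 1000)
  expect_equal(b1, b2)
})

test_that("chained block sums cover member matches", {
  b <- chain_synteny_blocks(paf_records(data.frame(
    qname = "s1", qlen = 1e5, qstart = c(0, 10000, 21000),
    qend = c(9000, 20000, 30000), strand = "+", tname = "c1", tlen = 2e5,
    tstart = c(0, 10000, 21000), tend = c(9000, 20000, 30000),
    nmatch = c(8000, 9000, 8500), blocklen = 9000, mapq = 60,
    stringsAsFactors = FALSE)), max_gap = 5000, min_block = 1000)
  expect_equal(nrow(b), 1)
  expect_equal(b$aligned, 25500)
  expect_equal(b$n_aln, 3)
})

test_that("anchoring follows strict-majority aligned bases with tie -> unplaced", {
  blocks <- rbind(
    make_blocks(3, qname = "s1", chrom = "chrA"),
    make_blocks(1, qname = "s1", chrom = "chrB"),
    make_blocks(2, qname = "s2", chrom = "chrB"))
  res <- anchor_scaffolds(blocks, c(s1 = 40000, s2 = 20000, s3 = 5000))
  expect_equal(res$placements$chrom[res$placements$scaffold == "s1"], "chrA")
  expect_equal(res$placements$chrom[res$placements$scaffold == "s2"], "chrB")
  expect_true("s3" %in% res$unplaced) # zero blocks
  expect_equal(res$anchored_fraction, 60000 / 65000)
  # exact 50/50 split: no strict majority
  tie <- rbind(make_blocks(2, qname = "t1", chrom = "chrA"),
               make_blocks(2, qname = "t1", chrom = "chrB"))
  res2 <- anchor_scaffolds(tie, c(t1 = 40000))
  expect_true("t1" %in% res2$unplaced)
})

test_that("anchoring recovers the true origin of a fragmented assembly", {
  g <- simulate_genome(2, 300000, seed = 111)
  fr <- plant_misassemblies(g, fragment_n50_target = 60000, seed = 112)
  seg <- fr$layout[fr$layout$type == "segment", ]
  blocks <- data.frame(
    qname = seg$seq_id, qstart = 0, qend = seg$dend - seg$dstart,
    tname = seg$src, tstart = seg$sstart, tend = seg$send, strand = "+",
    aligned = seg$send - seg$sstart, n_aln = 1, stringsAsFactors = FALSE)
  res <- anchor_scaffolds(blocks, seq_lengths(fr$sequences))
  expect_equal(res$anchored_fraction, 1)
  expect_equal(nrow(res$placements), nrow(seg))
  # chromosome, order and orientation all correct
  expect_equal(res$placements$chrom,
               seg$src[match(res$placements$scaffold, seg$seq_id)])
  for (ch in unique(seg$src)) {
    truth_order <- seg$seq_id[seg$src == ch][order(seg$sstart[seg$src == ch])]
    expect_equal(res$placements$scaffold[res$placements$chrom == ch], truth_order)
  }
  expect_true(all(res$placements$orientation == "+"))
  expect_s3_class(res$assembly, "agp")
})

test_that("collinearity verification honors the either-evidence disjunction", {
  jn <- data.frame(seq_id = "s1", pos = 50000)
  spanning <- make_blocks(1, qname = "s1", block = 100000)
  split_ev <- rbind(make_blocks(1, qname = "s1", block = 40000),
                    make_blocks(1, qname = "s1", chrom = "chrB", block = 100000)[1, ])
  split_ev$qstart[2] <- 60000; split_ev$qend[2] <- 99000
  split_ev$tstart[2] <- 0; split_ev$tend[2] <- 39000
  # single spanning block -> verified
  expect_equal(verify_collinearity(jn, list(spanning))$verdict, "verified")
  # both evidence sets switch chromosomes at the junction -> unverified
  expect_equal(verify_collinearity(jn, list(split_ev, split_ev))$verdict,
               "unverified")
  # unverified by one set but spanned by the other -> verified
  expect_equal(verify_collinearity(jn, list(split_ev, spanning))$verdict,
               "verified")
  # two adjacent order-consistent same-chromosome blocks -> verified
  adj <- rbind(make_blocks(1, qname = "s1", block = 49000),
               make_blocks(1, qname = "s1", block = 49000))
  adj$qstart <- c(0, 51000); adj$qend <- c(49900, 99000)
  adj$tstart <- c(0, 51000); adj$tend <- c(49900, 99000)
  expect_equal(verify_collinearity(jn, list(adj))$verdict, "verified")
  # monotone in evidence: adding a set never flips verified -> unverified
  for (ev in list(list(spanning), list(split_ev))) {
    v1 <- verify_collinearity(jn, ev)$verdict
    v2 <- verify_collinearity(jn, c(ev, list(spanning)))$verdict
    expect_false(v1 == "verified" && v2 == "unverified")
  }
})

test_that("rearrangement counting matches planted events exactly", {
  expect_equal(count_rearrangements(make_blocks(10))$intra, 0)
  expect_equal(count_rearrangements(make_blocks(10))$inter, 0)
  one_inv <- count_rearrangements(make_blocks(9, inv_runs = list(5)))
  expect_equal(one_inv$intra, 1)
  expect_equal(one_inv$events$kind, "inversion")
  for (k in 1:10) {
    runs <- lapply(seq_len(k), function(i) (3 * i - 1):(3 * i))
    r <- count_rearrangements(make_blocks(3 * k + 5, inv_runs = runs))
    expect_equal(r$intra, k)
    expect_true(all(r$events$kind == "inversion"))
  }
  mv <- count_rearrangements(make_blocks(10, move = 4))
  expect_equal(mv$inter, 1)
  expect_equal(mv$intra, 0)
})

test_that("event counts equal the exhaustive-subset oracle on all permutations", {
  for (n in 2:6) {
    for (perm in all_permutations(n)) {
      b <- make_blocks(n)
      b$tstart <- (perm - 1) * 10000
      b$tend <- b$tstart + 9000
      got <- count_rearrangements(b)$intra
      want <- oracle_rearrangement_events((b$tstart + b$tend) / 2, b$strand)
      expect_equal(got, want,
                   label = sprintf("perm %s", paste(perm, collapse = ",")))
    }
  }
})

test_that("event counts match the oracle on random signed permutations", {
  set.seed(121)
  for (rep in 1:300) {
    n <- sample(2:6, 1)
    b <- make_blocks(n)
    perm <- sample(n)
    b$tstart <- (perm - 1) * 10000
    b$tend <- b$tstart + 9000
    flip <- stats::runif(n) < 0.3
    b$strand[flip] <- "-"
    got <- count_rearrangements(b)$intra
    want <- oracle_rearrangement_events((b$tstart + b$tend) / 2, b$strand)
    expect_equal(got, want,
                 label = sprintf("perm %s strand %s",
                                 paste(perm, collapse = ","),
                                 paste(b$strand, collapse = "")))
  }
})

test_that("breakpoint profiles normalize distance to the nearest end", {
  lens <- c(chrA = 1e6)
  near <- data.frame(chrom = "chrA", pos = c(1e4, 2e4, 9.9e5))
  prof <- breakpoint_position_profile(near, lens, n_bins = 10)
  expect_equal(prof$freq[1], 1)
  expect_equal(sum(prof$freq), 1)
  # uniform breakpoints fill bins evenly
  set.seed(131)
  unif <- data.frame(chrom = "chrA", pos = runif(5000, 0, 1e6))
  pu <- breakpoint_position_profile(unif, lens, n_bins = 5)
  expect_true(all(abs(pu$freq - 0.2) < 3 * sqrt(0.2 * 0.8 / 5000)))
  # empty report
  r0 <- count_rearrangements(make_blocks(5))
  expect_equal(nrow(breakpoint_position_profile(r0, lens)), 0)
  expect_error(breakpoint_position_profile(
    data.frame(chrom = "chrA", pos = 2e6), lens), "outside")
})
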