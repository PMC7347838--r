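# reads-vs-contigs fixture: one read spanning the junction tail(A)-head(B)
spanning_read <- function(rid = "r1", gap = 100, over_a = 200, over_b = 300,
                          lenA = 5000, lenB = 4000) {
  # read covers last over_a bases of A, the gap, first over_b bases of B
  rlen <- over_a + gap + over_b
  paf_records(data.frame(
    qname = rid, qlen = rlen, qstart = c(0, over_a + gap),
    qend = c(over_a, rlen), strand = "+", tname = c("A", "B"),
    tlen = c(lenA, lenB), tstart = c(lenA - over_a, 0),
    tend = c(lenA, over_b), nmatch = c(over_a, over_b),
    blocklen = c(over_a, over_b), mapq = 60, stringsAsFactors = FALSE))
}

test_that("a single spanning read creates a retained link with its implied gap", {
  aln <- spanning_read(gap = 100)
  g <- build_link_graph(aln, c(A = 5000, B = 4000), min_reads = 1)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$support, 1)
  expect_setequal(c(paste(g$edges$contig1, g$edges$end1),
                    paste(g$edges$contig2, g$edges$end2)),
                  c("A tail", "B head"))
  expect_equal(g$edges$gaps[[1]], 100)
  # three reads with different implied gaps aggregate on one edge
  aln3 <- do.call(rbind, list(spanning_read("r1", 90), spanning_read("r2", 100),
                              spanning_read("r3", 300)))
  g3 <- build_link_graph(aln3, c(A = 5000, B = 4000))
  expect_equal(g3$edges$support, 3)
  expect_setequal(g3$edges$gaps[[1]], c(90, 100, 300))
  # reads touching one contig only -> empty graph
  g0 <- build_link_graph(aln_row("r9", "A", 0, 1000), c(A = 5000, B = 4000))
  expect_equal(nrow(g0$edges), 0)
})

test_that("the synteny guard removes violating links and is idempotent", {
  aln <- rbind(spanning_read("r1"),
               local({ x <- spanning_read("r2"); x$tname <- c("A", "C"); x }),
               local({ x <- spanning_read("r3"); x$tname <- c("A", "U"); x }))
  g <- build_link_graph(aln, c(A = 5000, B = 4000, C = 4000, U = 4000))
  guard <- data.frame(contig = c("A", "B", "C", "D"),
                      chrom = c("chr1", "chr2", "chr1", "chr1"),
                      pos = c(1e6, 5e5, 1.2e6, 1.1e6), stringsAsFactors = FALSE)
  f <- filter_links_by_synteny(g, guard)
  # A(chr1)-B(chr2) removed; A(chr1:1M)-C(chr1:1.2M) removed because the
  # anchored contig D sits strictly between; A-U kept (U unanchored)
  expect_equal(nrow(f$edges), 1)
  expect_true("U" %in% c(f$edges$contig1, f$edges$contig2))
  expect_setequal(f$removed$reason, c("inter_chromosome", "skipped_anchor"))
  # without D in between, A-C survives
  f2 <- filter_links_by_synteny(g, guard[guard$contig != "D", ])
  expect_true(any(c(f2$edges$contig1, f2$edges$contig2) == "C"))
  # idempotence
  ff <- filter_links_by_synteny(f, guard)
  expect_equal(ff$edges, f$edges)
})

test_that("linearization keeps end degrees at one and resolves conflicts by support", {
  # Y-fork: B tail claimed by both C (3 reads) and D (1 read)
  mk <- function(rid, a, b, lens) {
    x <- spanning_read(rid, lenA = lens[[a]], lenB = lens[[b]])
    x$tname <- c(a, b); x
  }
  lens <- c(A = 5000, B = 4000, C = 3000, D = 2500)
  aln <- rbind(mk("r1", "A", "B", lens),
               mk("r2", "B", "C", lens), mk("r3", "B", "C", lens),
               mk("r4", "B", "C", lens), mk("r5", "B", "D", lens))
  g <- build_link_graph(aln, lens)
  lin <- linearize_scaffolds(g)
  # every contig placed exactly once
  expect_setequal(lin$paths$contig, names(lens))
  expect_equal(anyDuplicated(lin$paths$contig), 0)
  adj <- recovered_adjacencies(lin$paths)
  expect_true(paste("B", "C") %in% paste(adj$left, adj$right) ||
                paste("C", "B") %in% paste(adj$left, adj$right))
  expect_equal(nrow(lin$conflicts), 1)
  expect_equal(lin$conflicts$reason, "end_in_use")
  # D is cut off the fork: no join touches it
  expect_false("D" %in% c(adj$left, adj$right))
})

test_that("three-contig cycles drop the weakest edge on every support pattern", {
  lens <- c(A = 5000, B = 4000, C = 3000)
  mk <- function(rid, a, b) {
    x <- spanning_read(rid, lenA = lens[[a]], lenB = lens[[b]])
    x$tname <- c(a, b); x
  }
  # enumerate support multiplicities 1..3 for the three cycle edges
  for (sa in 1:3) for (sb in 1:3) for (sc in 1:3) {
    rows <- list(); rid <- 0
    for (i in seq_len(sa)) { rid <- rid + 1; rows[[rid]] <- mk(paste0("r", rid), "A", "B") }
    for (i in seq_len(sb)) { rid <- rid + 1; rows[[rid]] <- mk(paste0("r", rid), "B", "C") }
    for (i in seq_len(sc)) { rid <- rid + 1; rows[[rid]] <- mk(paste0("r", rid), "C", "A") }
    g <- build_link_graph(do.call(rbind, rows), lens)
    expect_equal(nrow(g$edges), 3)
    lin <- linearize_scaffolds(g)
    # a path, not a cycle: exactly 2 joins, one rejected edge
    expect_equal(nrow(lin$joins), 2)
    expect_equal(nrow(lin$conflicts), 1)
    expect_equal(lin$conflicts$reason, "would_close_cycle")
    sup <- c(sa, sb, sc)
    expect_lte(lin$conflicts$support, min(sup[-which.max(sup)]))
    # degree constraint
    ends <- c(paste(lin$joins$left_contig), paste(lin$joins$right_contig))
    expect_true(all(table(ends) <= 2))
  }
})

test_that("fragmented chromosomes are reassembled with correct order and orientation", {
  g1 <- simulate_genome(1, 1000000, seed = 91)
  fr <- plant_misassemblies(g1, fragment_n50_target = 25000, seed = 92)
  lr <- simulate_long_reads(g1, coverage = 30, mean_len = 10000, len_sd = 1000,
                            error_rate = 0, seed = 93)
  la <- lift_alignments(lr$truth, fr$layout)
  gr <- build_link_graph(la, seq_lengths(fr$sequences))
  lin <- linearize_scaffolds(gr)
  expect_gte(adjacency_recall(lin$paths, fr$layout), 0.95)
  # gap estimates for directly adjacent fragments are floored at 10
  expect_true(all(lin$joins$gap_est >= 10))
  # scaffold sequence length ~ chromosome length plus inserted gaps
  sc <- scaffold_sequences(lin, fr$sequences)
  expect_gte(max(nchar(sc)), 0.99 * 1e6)
})

test_that("the guard blocks all inter-chromosome joins on a two-chromosome mix", {
  g2 <- simulate_genome(2, 400000, seed = 94)
  fr <- plant_misassemblies(g2, fragment_n50_target = 30000, seed = 95)
  lr <- simulate_long_reads(g2, coverage = 25, mean_len = 10000, len_sd = 1000,
                            error_rate = 0, seed = 96)
  la <- lift_alignments(lr$truth, fr$layout)
  gr <- build_link_graph(la, seq_lengths(fr$sequences))
  seg <- fr$layout[fr$layout$type == "segment", ]
  guard <- data.frame(contig = seg$seq_id, chrom = seg$src, pos = seg$sstart,
                      stringsAsFactors = FALSE)
  lin <- linearize_scaffolds(filter_links_by_synteny(gr, guard))
  adj <- recovered_adjacencies(lin$paths)
  chrom_of <- setNames(seg$src, seg$seq_id)
  expect_equal(sum(chrom_of[adj$left] != chrom_of[adj$right]), 0)
})
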