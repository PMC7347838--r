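test_that("simulated genomes carry telomeric termini and requested GC", {
  g <- simulate_genome(2, 100000, telomere_units = 10, seed = 7)
  expect_true(all(startsWith(g, strrep("CCCTAA", 10))))
  expect_true(all(endsWith(g, strrep("TTAGGG", 10))))
  # determinism
  expect_identical(g, simulate_genome(2, 100000, telomere_units = 10, seed = 7))
  expect_false(identical(g, simulate_genome(2, 100000, telomere_units = 10,
                                            seed = 8)))
  # interior GC within 3 binomial SDs
  g2 <- simulate_genome(1, 1e6, telomere_units = 10, gc = 0.5, seed = 3)
  inner <- substring(g2, 61, 1e6 - 60)
  n <- nchar(inner)
  gc_obs <- (lengths(regmatches(inner, gregexpr("[GC]", inner)))) / n
  expect_lt(abs(gc_obs - 0.5), 3 * sqrt(0.25 / n))
  expect_error(simulate_genome(1, 100, telomere_units = 10), "too short")
})

test_that("long-read simulation hits coverage and is exact at error 0", {
  g <- simulate_genome(2, 250000, seed = 2)
  lr <- simulate_long_reads(g, coverage = 20, mean_len = 8000, len_sd = 800,
                            error_rate = 0, seed = 5)
  tot <- sum(nchar(lr$reads))
  expect_gte(tot, 0.95 * 20 * 500000)
  expect_lte(tot, 1.05 * 20 * 500000)
  expect_equal(unname(lr$truth$mapq), rep(60, nrow(lr$truth)))
  # every read equals its truth interval after strand handling
  tr <- lr$truth
  sl <- substring(g[tr$tname], tr$tstart + 1, tr$tend)
  sl[tr$strand == "-"] <- revcomp(sl[tr$strand == "-"])
  expect_identical(unname(lr$reads[tr$qname]), unname(sl))
  # seeded reproducibility
  expect_identical(lr$reads,
                   simulate_long_reads(g, 20, 8000, 800, 0, seed = 5)$reads)
  expect_error(simulate_long_reads(g, 1, mean_len = 1e6), "longest chromosome")
})

test_that("substitution errors hit the requested rate", {
  g <- simulate_genome(1, 200000, seed = 9)
  lr <- simulate_long_reads(g, coverage = 5, mean_len = 5000, len_sd = 500,
                            error_rate = 0.05, seed = 10)
  tr <- lr$truth
  sl <- substring(g[tr$tname], tr$tstart + 1, tr$tend)
  sl[tr$strand == "-"] <- revcomp(sl[tr$strand == "-"])
  mism <- mapply(function(a, b) {
    sum(utf8ToInt(a) != utf8ToInt(b))
  }, unname(lr$reads[tr$qname]), sl)
  rate <- sum(mism) / sum(tr$qlen)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / sum(tr$qlen)))
  expect_equal(unname(tr$nmatch), unname(tr$qlen - mism))
})

test_that("gel-free mate-pair mixture has multinomial component counts", {
  g <- simulate_genome(1, 500000, seed = 1)
  mix <- insert_mixture(c(0.5, 0.5), c(300, 3000), c(30, 300),
                        c("inward", "outward"))
  mp <- simulate_gelfree_matepairs(g, 10000, mix, read_len = 100, seed = 4)
  counts <- table(mp$pairs$component)
  expect_true(all(abs(counts - 5000) < 3 * sqrt(10000 * 0.25)))
  expect_equal(nrow(mp$truth), 20000)
  # mapped-end orientations follow the component convention
  tr <- mp$truth
  m1 <- tr[match(paste0(mp$pairs$pair_id, "/1"), tr$qname), ]
  m2 <- tr[match(paste0(mp$pairs$pair_id, "/2"), tr$qname), ]
  expect_true(all(m1$strand[mp$pairs$orientation == "inward"] == "+"))
  expect_true(all(m2$strand[mp$pairs$orientation == "outward"] == "+"))
  # outer span equals the recorded insert
  expect_equal(unname(pmax(m1$tend, m2$tend) - pmin(m1$tstart, m2$tstart)),
               mp$pairs$insert)
  expect_equal(nrow(simulate_gelfree_matepairs(g, 0, mix)$pairs), 0)
  single <- insert_mixture(1, 3000, 300, "outward")
  mp1 <- simulate_gelfree_matepairs(g, 50, single, seed = 2)
  expect_true(all(mp1$pairs$orientation == "outward"))
  expect_error(insert_mixture(c(0.5, 0.6), c(300, 3000), c(30, 300),
                              c("inward", "outward")), "sum to 1")
})

test_that("planted misassemblies conserve bases and record truth", {
  g <- simulate_genome(3, 150000, seed = 6)
  pm <- plant_misassemblies(g, n_fusion = 5, fragment_n50_target = 30000,
                            n_true_joins = 3, seed = 7)
  expect_equal(sum(pm$events$kind == "fusion"), 5)
  expect_equal(sum(pm$events$kind == "join"), 3)
  # every breakpoint lies inside its derived sequence
  lens <- seq_lengths(pm$sequences)
  expect_true(all(pm$breakpoints$pos > 0 &
                    pm$breakpoints$pos < lens[pm$breakpoints$seq_id]))
  # non-N base multiset conserved (no inversions planted here)
  count_bases <- function(x) {
    tab <- table(strsplit(paste(x, collapse = ""), "")[[1]])
    tab[setdiff(names(tab), "N")]
  }
  expect_equal(count_bases(pm$sequences), count_bases(g))
  # zero events -> plain fragmentation, no gaps, nothing recorded
  fr <- plant_misassemblies(g, fragment_n50_target = 30000, seed = 8)
  expect_equal(nrow(fr$events), 0)
  expect_equal(nrow(n_run_ranges(fr$sequences)), 0)
  expect_equal(sum(nchar(fr$sequences)), sum(nchar(g)))
})

test_that("inversions and translocations conserve strand-pooled base counts", {
  g <- simulate_genome(3, 120000, seed = 11)
  pm <- plant_misassemblies(g, n_inversion = 3, n_translocation = 2,
                            fragment_n50_target = 40000, seed = 12)
  expect_equal(sum(pm$events$kind == "inversion"), 3)
  expect_equal(sum(pm$events$kind == "translocation"), 2)
  pooled <- function(x) {
    tab <- table(strsplit(paste(x, collapse = ""), "")[[1]])
    gv <- function(b) if (b %in% names(tab)) unname(tab[[b]]) else 0
    c(at = gv("A") + gv("T"), gc = gv("G") + gv("C"))
  }
  expect_equal(pooled(pm$sequences), pooled(g))
  expect_equal(sum(nchar(gsub("N", "", pm$sequences))),
               sum(nchar(g)))
})

test_that("lifted truth alignments reproduce read sequences on the derived assembly", {
  g <- simulate_genome(2, 100000, seed = 21)
  pm <- plant_misassemblies(g, n_fusion = 2, fragment_n50_target = 25000,
                            n_true_joins = 2, seed = 22)
  lr <- simulate_long_reads(g, coverage = 3, mean_len = 5000, len_sd = 500,
                            error_rate = 0, seed = 23)
  la <- lift_alignments(lr$truth, pm$layout)
  # each lifted record's target slice (gaps removed) must equal the read slice
  for (i in seq_len(min(nrow(la), 200))) {
    r <- la[i, ]
    tgt <- substring(pm$sequences[[r$tname]], r$tstart + 1, r$tend)
    tgt <- gsub("N", "", tgt)
    rd <- substring(lr$reads[[r$qname]], r$qstart + 1, r$qend)
    if (r$strand == "-") rd <- revcomp(rd)
    expect_identical(rd, tgt)
  }
  expect_true(all(la$mapq == 60))
})

test_that("marker maps plant the exact discordant count", {
  g <- simulate_genome(4, 100000, seed = 2)
  mm <- simulate_marker_map(g, 2166, 4 / 2166, seed = 3)
  expect_equal(sum(mm$discordant), 4)
  grp <- sub("LG0?", "chr0", mm$linkage_group) # group k <-> chromosome k
  expect_true(all((grp == mm$chrom) == !mm$discordant))
  # concordant markers: genetic order follows physical order
  conc <- mm[!mm$discordant, ]
  for (ch in unique(conc$chrom)) {
    m <- conc[conc$chrom == ch, ]
    expect_true(all(diff(m$cM[order(m$pos)]) >= 0))
  }
  expect_equal(sum(simulate_marker_map(g, 500, 0, seed = 4)$discordant), 0)
  expect_identical(mm, simulate_marker_map(g, 2166, 4 / 2166, seed = 3))
  expect_error(simulate_marker_map(g, 0, 0), "n_markers")
})

test_that("psg tables are uniform under the null and Beta under selection", {
  tab <- simulate_psg_table(2000, frac_selected = 0, seed = 5)
  # KS statistic below the asymptotic 99th-percentile null cutoff
  for (cc in c("pA_gap", "pA_nogap", "pB_gap", "pB_nogap")) {
    ks <- suppressWarnings(stats::ks.test(tab[[cc]], "punif"))
    expect_lt(unname(ks$statistic), 1.63 / sqrt(2000))
  }
  # closed-form pass rate under full selection:
  # P(one test < .05) = 0.05^alt, P(>=3 of 4) via binomial
  alt <- 0.05
  p1 <- 0.05^alt
  expect_rate <- stats::pbinom(2, 4, p1, lower.tail = FALSE)
  tab2 <- simulate_psg_table(4000, frac_selected = 1, alt_strength = alt,
                             seed = 6)
  pass <- rowSums(as.matrix(tab2[, 2:5]) < 0.05) >= 3
  expect_lt(abs(mean(pass) - expect_rate),
            3 * sqrt(expect_rate * (1 - expect_rate) / 4000))
  expect_identical(tab, simulate_psg_table(2000, frac_selected = 0, seed = 5))
})
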