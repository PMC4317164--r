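test_that("bootstrap profiles are deterministic and degenerate correctly", {
  m <- matrix(rep(c(0.2, 0.8, 0.5), each = 10), 10, 3)
  p <- bootstrap_profile(m, B = 200, seed = 4)
  expect_equal(p$lo, p$mean)          # identical vectors: zero variance
  expect_equal(p$hi, p$mean)
  expect_equal(p$mean, c(0.2, 0.8, 0.5))
  p2 <- bootstrap_profile(m, B = 200, seed = 4)
  expect_identical(p, p2)
  expect_error(bootstrap_profile(matrix(0, 0, 3)), "empty")
})

test_that("bootstrap CI matches an independent resampler on 0/1 vectors", {
  m <- rbind(matrix(0, 20, 5), matrix(1, 20, 5))
  p <- bootstrap_profile(m, B = 2000, seed = 9)
  expect_equal(p$mean, rep(0.5, 5))
  # oracle: direct binomial bootstrap of the mean of 40 draws from {0,1}
  set.seed(1234)
  boots <- rbinom(2000, 40, 0.5) / 40
  o_lo <- quantile(boots, 0.05); o_hi <- quantile(boots, 0.95)
  expect_lt(max(abs(p$lo - o_lo)), 0.05)
  expect_lt(max(abs(p$hi - o_hi)), 0.05)
})

test_that("CI half-width scales as 1/sqrt(n) on i.i.d. fixtures", {
  set.seed(5)
  hw <- vapply(c(25, 100, 400), function(n) {
    m <- matrix(rnorm(n * 4), n, 4)
    p <- bootstrap_profile(m, B = 600, seed = 11)
    mean(p$hi - p$lo)
  }, numeric(1))
  expect_gt(hw[1] / hw[2], 2 * 0.8)
  expect_lt(hw[1] / hw[2], 2 * 1.2)
  expect_gt(hw[2] / hw[3], 2 * 0.8)
  expect_lt(hw[2] / hw[3], 2 * 1.2)
})

test_that("mean-score classification splits high/low tails", {
  trk <- score_track(list(chr1 = c(rep(1, 50), rep(0, 50),
                                   rep(c(1, 0), 25))))
  ex <- data.frame(exon_id = c("chr1:0-50:+", "chr1:50-100:+",
                               "chr1:100-150:+"))
  r <- mean_score_classify(ex, trk)
  expect_equal(r$per_exon$mean_score, c(1, 0, 0.5))
  expect_equal(r$fractions$frac_high, 1 / 3)
  expect_equal(r$fractions$frac_low, 1 / 3)
})

test_that("heavily missing exons are dropped from score classification", {
  v <- c(rep(NA, 40), rep(1, 10), rep(1, 50))
  trk <- score_track(list(chr1 = v))
  ex <- data.frame(exon_id = c("chr1:0-50:+", "chr1:50-100:+"))
  r <- mean_score_classify(ex, trk)
  expect_true(r$per_exon$dropped[1])     # 80% missing
  expect_false(r$per_exon$dropped[2])
})

test_that("window entropy matches the closed form and excludes gaps", {
  five <- matrix("A", 5, 6)
  expect_equal(entropy_window(five), 0)
  split32 <- five
  split32[, 3] <- c("A", "A", "A", "C", "C")   # 3/2 split in one column
  expect_equal(entropy_window(split32),
               -(0.6 * log(0.6) + 0.4 * log(0.4)), tolerance = 1e-12)
  gapped <- five; gapped[2, 4] <- "-"
  expect_true(is.na(entropy_window(gapped)))
  # bounds: 0 <= H <= k*ln(4); invariant under row permutation
  set.seed(8)
  for (i in 1:50) {
    m <- matrix(sample(c("A", "C", "G", "T"), 30, replace = TRUE), 5, 6)
    h <- entropy_window(m)
    expect_gte(h, 0)
    expect_lte(h, 6 * log(4) + 1e-12)
    expect_equal(entropy_window(m[sample(5), ]), h)
  }
})

test_that("entropy agrees with a brute-force column counter to 1e-12", {
  set.seed(21)
  for (i in 1:1000) {
    m <- matrix(sample(c("A", "C", "G", "T"), 24, replace = TRUE), 4, 6)
    if (i %% 7 == 0) m[sample(24, 1)] <- "-"
    expect_equal(entropy_window(m), oracle_entropy(m), tolerance = 1e-12)
  }
})

test_that("conserved k-mer scanning slides gapless sub-threshold windows", {
  seqs <- c(human = strrep("ACGTT", 4), mouse = strrep("ACGTT", 4),
            dog = strrep("ACGTT", 4))
  b <- msa_block(seqs, "r1", flank5 = 5, flank3 = 5)
  sc <- conserved_kmer_scan(b)
  expect_equal(nrow(sc), 20 - 6 + 1)      # fully conserved: L - k + 1
  expect_true(all(sc$entropy == 0))
  expect_equal(sc$kmer[1], "ACGTTA")
  # a divergent stretch lifts entropy above threshold
  # columns 8-13 get three distinct bases each (entropy ln 3 > 1 per column)
  seqs2 <- seqs
  substr(seqs2["mouse"], 8, 13) <- "ACCTTA"
  substr(seqs2["dog"], 8, 13) <- "CAGCGT"
  sc2 <- conserved_kmer_scan(msa_block(seqs2, "r2", flank5 = 5, flank3 = 5))
  expect_true(all(sc2$position > 13 | sc2$position < 3))
  # missing reference row errors
  b3 <- msa_block(seqs, "r3", ref = "mouse", flank5 = 5, flank3 = 5)
  b3$ref <- "human2"
  expect_error(conserved_kmer_scan(b3), "reference")
})

test_that("planted TGCATG is the top conserved 6-mer in AS 3' flanks", {
  sim <- shared_sim()
  blocks <- make_msa_blocks(sim, seed = 3)
  scans <- lapply(blocks, conserved_kmer_scan)
  tm <- sim$truth$micro
  labels <- setNames(ifelse(tm$type == "CS", "CS", "AS"), tm$exon_id)
  enr <- conserved_kmer_enrichment(scans, labels)
  as3 <- enr[enr$label == "AS" & enr$region == "3-intron", ]
  expect_equal(as3$kmer[which.max(as3$mean_per_exon)], "TGCATG")
  # duplicating every exon leaves the means unchanged
  enr2 <- conserved_kmer_enrichment(c(scans, setNames(scans, paste0(names(scans), "b"))),
                                    c(labels, setNames(labels, paste0(names(labels), "b"))))
  m1 <- enr[order(enr$label, enr$region, enr$kmer), "mean_per_exon"]
  m2 <- enr2[order(enr2$label, enr2$region, enr2$kmer), "mean_per_exon"]
  expect_equal(m1, m2)
})

test_that("MSA blocks round-trip through multi-FASTA", {
  sim <- shared_sim()
  blocks <- make_msa_blocks(sim, seed = 3)
  path <- tempfile(fileext = ".fa")
  write_msa_fasta(blocks[1:3], path)
  back <- read_msa_fasta(path, flank5 = 250, flank3 = 250)
  expect_equal(names(back), names(blocks)[1:3])
  expect_equal(back[[1]]$seqs, blocks[[1]]$seqs)
})

test_that("percent identity counts gaps as mismatches and is reflexive", {
  x <- strrep("ACGT", 25)
  expect_equal(percent_identity(x, x), 100)
  y <- x; substr(y, 50, 50) <- "T"   # one substitution (A at 50 -> T)
  expect_equal(percent_identity(x, y), 99)
  a <- "ACGTACGTACGT"; b <- "ACCTAC--ACGA"   # 12 cols, 3 mismatching + gaps
  regions <- rep("exon-edge", 12)
  expect_equal(percent_identity(substr(a, 1, 12), b, regions, "exon-edge"),
               100 * 8 / 12)
  expect_true(is.na(percent_identity(a, a, regions, "absent")))
})

test_that("coverage metagenes are flat on uniform tracks and linear", {
  trk <- score_track(list(chr1 = rep(3, 1000)))
  ex <- data.frame(exon_id = "chr1:490-510:+", label = "x")
  mg <- coverage_metagene(trk, ex, window = 100, B = 50, seed = 2)
  expect_true(all(mg$x$mean == 3))
  trk2 <- score_track(list(chr1 = rep(6, 1000)))
  mg2 <- coverage_metagene(trk2, ex, window = 100, B = 50, seed = 2)
  expect_equal(mg2$x$mean, 2 * mg$x$mean)
  expect_warning(coverage_metagene(trk, ex[0, , drop = FALSE], window = 100,
                                   B = 10), "empty")
})

test_that("replicate coverage tracks are merged before profiling", {
  t1 <- score_track(list(chr1 = rep(2, 500)))
  t2 <- score_track(list(chr1 = rep(4, 500)))
  ex <- data.frame(exon_id = "chr1:240-260:+", label = "x")
  mg <- coverage_metagene(list(t1, t2), ex, window = 60, B = 20, seed = 1)
  expect_true(all(mg$x$mean == 3))
})

test_that("AS-planted coverage peaks separate AS from CS downstream", {
  sim <- shared_sim()
  cov <- make_coverage_track(sim, seed = 13)
  tm <- sim$truth$micro
  ex <- data.frame(exon_id = tm$exon_id,
                   label = ifelse(tm$type == "CS", "CS", "AS"))
  mg <- coverage_metagene(cov, ex, window = 300, B = 100, seed = 5)
  dn <- mg$AS$position > 20
  expect_gt(mean(mg$AS$mean[dn]), mean(mg$CS$mean[dn]))
})

test_that("score tracks round-trip through bedGraph", {
  sim <- shared_sim()
  trk <- make_score_track(sim, seed = 3)
  sub <- score_track(trk$scores[1:2])
  path <- tempfile(fileext = ".bedgraph")
  write_score_track(sub, path)
  lens <- vapply(sub$scores, length, integer(1))
  back <- read_score_track(path, lens)
  expect_equal(back$scores[[1]], sub$scores[[1]], tolerance = 1e-6)
})
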