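test_that("ESE density counts overlapping hexamer starts over L-5 windows", {
  expect_equal(ese_density("GAAGAAGAAGAA", "GAAGAA"), 3 / 7)
  expect_equal(ese_density("GAAGAA", "GAAGAA"), 1)
  expect_equal(ese_density("ACGTACGTACGT", character(0)), 0)
  expect_message(d <- ese_density("ACGT", "GAAGAA"), "shorter")
  expect_true(is.na(d))
})

test_that("ESE density is bounded and monotone in the hexamer set", {
  set.seed(42)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
    set1 <- c("GAAGAA", "TTTTTT")
    set2 <- c(set1, substr(s, 7, 12))
    d1 <- ese_density(s, set1); d2 <- ese_density(s, set2)
    expect_true(d1 >= 0 && d1 <= 1)
    expect_gte(d2, d1)
  }
})

perfect_pwm <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  p <- matrix(0, length(chars), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  p[cbind(seq_along(chars), match(chars, colnames(p)))] <- 1
  pwm(p, "perfect")
}

uniform_pwm <- function(w) {
  pwm(matrix(0.25, w, 4, dimnames = list(NULL, c("A", "C", "G", "T"))), "uniform")
}

test_that("PWM scanning applies the geometric-mean threshold", {
  pw <- perfect_pwm("TTTTTTT")
  hit <- pwm_scan("TTTTTTT", pw)
  expect_equal(hit$pos, 1)
  expect_equal(hit$score, 0)                     # log(1) summed
  expect_gte(0, 7 * log(0.6))
  # uniform PWM scores 7*log(0.25) < 7*log(0.6) everywhere
  expect_equal(nrow(pwm_scan(strrep("ACGT", 10), uniform_pwm(7))), 0)
  # too-short sequence: no windows
  expect_equal(nrow(pwm_scan("TTT", pw)), 0)
})

test_that("PWM rows must be probability distributions", {
  bad <- matrix(c(0.5, 0.5, 0.5, 0.5), 1, 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  expect_error(pwm(bad), "sum to 1")
})

test_that("hit sets survive a log-base change when the threshold moves too", {
  set.seed(7)
  probs <- matrix(stats::rgamma(28, 1), 7, 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
  probs <- probs / rowSums(probs)
  pw <- pwm(probs)
  s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  nat <- pwm_scan(s, pw, threshold = 7 * log(0.6))
  # recompute in base 10 by scaling the natural-log scores
  all_nat <- pwm_scan(s, pw, threshold = -Inf)
  base10_hits <- all_nat$pos[all_nat$score / log(10) >= 7 * log10(0.6)]
  expect_equal(nat$pos, base10_hits)
})

test_that("splice-site scoring is pluggable: log-odds PWM, table, function", {
  pw <- perfect_pwm("CAGGTAAGT")
  expect_equal(splice_site_score("CAGGTAAGT", pw), 9 * log2(1 / 0.25))
  expect_equal(splice_site_score("CAGGTAAGT", uniform_pwm(9)), 0)
  expect_equal(splice_site_score("CAGGTAAGT", c(CAGGTAAGT = 10.86)), 10.86)
  expect_equal(splice_site_score("ACGTACGTA", function(x) 5), 5)
  expect_error(splice_site_score("ACGT", pw), "length")
  expect_error(splice_site_score("ACGT", list(a = 1)), "unknown scorer")
})

test_that("PWM and hexamer file readers accept U/T and validate shape", {
  pf <- tempfile(fileext = ".pwm")
  writeLines(c("A\tC\tG\tU", "0.1\t0.2\t0.3\t0.4", "0.25\t0.25\t0.25\t0.25"),
             pf)
  pw <- read_pwm(pf)
  expect_equal(pw$width, 2)
  expect_equal(unname(pw$probs[1, "T"]), 0.4)
  hf <- tempfile()
  writeLines(c("GAAGAA", "uggaag", ""), hf)
  expect_setequal(read_hexamers(hf), c("GAAGAA", "TGGAAG"))
  writeLines("TOOLONGG", hf)
  expect_error(read_hexamers(hf), "invalid")
})

test_that("exon subregions resolve as whole / central / splice-site-adjacent", {
  s <- paste(rep(c("A", "C"), 50), collapse = "")       # length 100
  expect_equal(resolve_region(region_whole(), s), s)
  cen <- resolve_region(region_central(24), s)
  expect_equal(nchar(cen), 24)
  expect_equal(cen, substr(s, 39, 62))                  # centered, left-shifted
  ss <- resolve_region(region_ss_adjacent(12, 12), s)
  expect_equal(ss, paste0(substr(s, 1, 12), substr(s, 89, 100)))
})

test_that("class feature tables carry medians and Mann-Whitney p-values", {
  sim <- shared_sim()
  tm <- sim$truth$micro
  classes <- data.frame(exon_id = tm$exon_id,
                        label = ifelse(tm$type == "CS", "CS", "AS"))
  ft <- class_feature_table(classes, sim$model_true,
                            sim$config$ese_hexamers)
  # medians are self-consistent with the per-exon table
  m_cs <- ft$medians$median[ft$medians$label == "CS" &
                              ft$medians$feature == "intron5_len"]
  expect_equal(m_cs, median(ft$per_exon$intron5_len[ft$per_exon$label == "CS"]))
  # CS-type introns are built shorter than AS-type ones
  m_as <- ft$medians$median[ft$medians$label == "AS" &
                              ft$medians$feature == "intron5_len"]
  expect_lt(m_cs, m_as)
  # identical feature values across classes -> two-sided p = 1
  cl2 <- data.frame(exon_id = rep(c("a", "b"), 2), label = rep(c("x", "y"), each = 2))
  pe <- data.frame(exon_id = cl2$exon_id, label = cl2$label,
                   v = c(1, 2, 1, 2))
  p <- suppressWarnings(wilcox.test(pe$v[pe$label == "x"],
                                    pe$v[pe$label == "y"])$p.value)
  expect_equal(p, 1)
  # U statistic matches a naive rank comparison
  x <- ft$per_exon$intron5_len[ft$per_exon$label == "CS"]
  y <- ft$per_exon$intron5_len[ft$per_exon$label == "AS"]
  u_naive <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_wilcox <- suppressWarnings(wilcox.test(x, y)$statistic)
  expect_equal(unname(u_wilcox), u_naive)
})

test_that("thymine-content profiles hit 1.0 on all-T flanks and clip at exons", {
  g <- fill_seq(400)
  g <- set_sub(g, 150, paste0("GT", strrep("T", 46), "AG"))  # all-T upstream
  g <- set_sub(g, 224, paste0("GT", strrep("C", 72), "AG"))
  exons <- data.frame(contig = "chr1", start = c(100L, 200L, 300L),
                      end = c(150L, 224L, 380L), strand = "+",
                      gene_id = "g", transcript_id = "t1")
  m <- genome_model(c(chr1 = g), exons)
  me <- data.frame(exon_id = "chr1:200-224:+")
  pr <- nt_content_profile(me, m, flank = 60, base = "T", min_exons = 1)
  up <- pr[pr$position >= -46 & pr$position <= -3, ]
  expect_true(all(up$fraction == 1))
  # positions beyond the 50-nt intron are clipped (n = 0)
  expect_true(all(pr$n[pr$position < -50] == 0))
  dn <- pr[pr$position >= 3 & pr$position <= 50, ]
  expect_true(all(dn$fraction == 0))
})

test_that("random flanks give ~25% thymine within the binomial envelope", {
  sim <- shared_sim()
  tm <- sim$truth$micro
  me <- data.frame(exon_id = tm$exon_id[tm$type == "AS"])
  pr <- nt_content_profile(me, sim$model_true, flank = 80, min_exons = 4)
  ok <- !is.na(pr$fraction) & pr$position > 30    # away from planted motifs
  n <- pr$n[ok]
  dev <- abs(pr$fraction[ok] - 0.25)
  expect_true(mean(dev <= 3 * sqrt(0.25 * 0.75 / n)) > 0.95)
})

test_that("upstream-window motif occurrence counts distinct hit starts", {
  sim <- shared_sim()
  tm <- sim$truth$micro
  exons <- data.frame(exon_id = tm$exon_id,
                      label = ifelse(tm$type == "CS", "CS", "AS"))
  probs <- matrix(c(.01, .13, .01, .85), 7, 4, byrow = TRUE,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
  u2 <- pwm(probs, "U2AF2-like")
  mo <- motif_occurrence_window(exons, sim$model_true, u2)
  expect_equal(mo$summary$fraction_with_hit[mo$summary$label == "CS"], 1)
  # a no-hit motif yields mean 0
  never <- perfect_pwm("AAAAAAA")
  mo0 <- motif_occurrence_window(exons[1:3, ], sim$model_true, never,
                                 threshold = 0)
  expect_equal(mo0$summary$mean_hits, 0)
})

test_that("k-mer flank profiles localize single occurrences exactly", {
  g <- fill_seq(600)
  g <- set_sub(g, 150, "GT"); g <- set_sub(g, 198, "AG")
  g <- set_sub(g, 224, "GT"); g <- set_sub(g, 398, "AG")
  g <- set_sub(g, 224 + 29, "TGCATG")    # 30th downstream-intron base
  exons <- data.frame(contig = "chr1", start = c(100L, 200L, 400L),
                      end = c(150L, 224L, 500L), strand = "+",
                      gene_id = "g", transcript_id = "t1")
  m <- genome_model(c(chr1 = g), exons)
  kp <- kmer_flank_profile(data.frame(exon_id = "chr1:200-224:+",
                                      label = "AS"), m, flank = 100)
  pr <- kp$profile
  expect_equal(pr$count[pr$position == 30], 1)
  expect_equal(sum(pr$count), 1)
  # absent k-mer: all-zero profile
  kp0 <- kmer_flank_profile(data.frame(exon_id = "chr1:200-224:+",
                                       label = "AS"), m,
                            kmer = "AAAAAA", flank = 100)
  expect_equal(sum(kp0$profile$count), 0)
})

test_that("hypergeometric overlap matches exact enumeration (N <= 30)", {
  expect_equal(overlap_test(10, 5, 5, 5), 1 / choose(10, 5))
  expect_equal(overlap_test(10, 5, 5, 0), 1)
  for (N in c(5, 9, 14, 20, 26, 30)) {
    for (A in seq(0, N, by = 3)) {
      for (B in seq(0, N, by = 4)) {
        for (k in 0:min(A, B)) {
          expect_equal(overlap_test(N, A, B, k),
                       oracle_hyper_upper(N, A, B, k), tolerance = 1e-12)
        }
      }
    }
  }
  # monotone decreasing in the overlap for fixed margins
  ps <- vapply(0:10, function(k) overlap_test(40, 15, 12, k), numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
  expect_error(overlap_test(10, 5, 5, 6), "inconsistent")
})
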