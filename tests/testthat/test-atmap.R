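micro_df <- function(contig, starts, ends, tx = "t1", strand = "+") {
  data.frame(exon_id = sprintf("%s:%d-%d:%s", contig, starts, ends, strand),
             contig = contig, start = starts, end = ends, strand = strand,
             length = ends - starts, origin = "annotated",
             transcripts = tx, stringsAsFactors = FALSE)
}

aug_fixture <- function(micro_starts, micro_lens, contig_len = 2000) {
  ends <- micro_starts + micro_lens
  exons <- data.frame(contig = "chr1",
                      start = c(0L, micro_starts, contig_len - 200L),
                      end = c(100L, ends, contig_len - 100L),
                      strand = "+", gene_id = "g", transcript_id = "t1")
  model <- genome_model(c(chr1 = fill_seq(contig_len)), exons)
  list(model = model, mes = micro_df("chr1", micro_starts, ends))
}

test_that("isoform enumeration covers backbones plus within-cluster combos", {
  f1 <- aug_fixture(500L, 24L)
  expect_equal(nrow(build_augmented(f1$model, f1$mes)$isoforms), 2)

  f2 <- aug_fixture(c(500L, 574L), c(24L, 12L))      # gap 50: one cluster
  expect_equal(nrow(build_augmented(f2$model, f2$mes)$isoforms), 4)

  f3 <- aug_fixture(c(500L, 1100L), c(24L, 12L))     # gap 576: two clusters
  a3 <- build_augmented(f3$model, f3$mes)
  expect_equal(nrow(a3$isoforms), 4)                 # all-in/out + toggles
  expect_setequal(a3$isoforms$inclusion, c("11", "00", "01", "10"))
})

test_that("clustered enumeration equals brute-force 2^k on small clusters", {
  f <- aug_fixture(c(500L, 560L, 600L), c(24L, 12L, 9L))  # gaps 36, 28
  a <- build_augmented(f$model, f$mes)
  brute <- apply(expand.grid(0:1, 0:1, 0:1), 1, paste, collapse = "")
  expect_setequal(a$isoforms$inclusion, brute)
  # isoform sequence lengths are consistent with the inclusion vectors
  lens <- nchar(a$isoforms$seq)
  incl <- t(sapply(strsplit(a$isoforms$inclusion, ""), as.integer))
  expect_equal(lens, as.numeric(200 + incl %*% c(24, 12, 9)))
})

test_that("oversized clusters trigger the cap error", {
  starts <- seq(500L, by = 20L, length.out = 13L)
  f <- aug_fixture(starts, rep(6L, 13))
  expect_error(build_augmented(f$model, f$mes), "cap")
})

test_that("junction maps give isoform coordinates and skipped micro-exons", {
  f <- aug_fixture(500L, 24L)
  a <- build_augmented(f$model, f$mes)
  jin <- a$junctions[a$junctions$iso_id == "t1|1", ]
  jout <- a$junctions[a$junctions$iso_id == "t1|0", ]
  expect_equal(sort(jin$pos), c(100, 124))
  expect_equal(jout$pos, 100)
  expect_equal(jout$skipped, f$mes$exon_id)
})

test_that("junction counting honors the anchor rule and the min rule", {
  f <- aug_fixture(500L, 24L)
  a <- build_augmented(f$model, f$mes)
  refs <- setNames(a$isoforms$length, a$isoforms$iso_id)
  recs <- c(
    sam_record("rL1", "t1|1", 95, "12M", strrep("C", 12)),   # 6|6 on jn 100
    sam_record("rL2", "t1|1", 96, "12M", strrep("C", 12)),   # 5-nt left anchor
    sam_record("rR1", "t1|1", 119, "12M", strrep("C", 12)),  # spans jn 124
    sam_record("rS1", "t1|0", 95, "12M", strrep("C", 12)),   # skip junction
    sam_record("rS2", "t1|0", 95, "12M", strrep("C", 12)))
  sam <- write_toy_sam(recs, refs)
  cts <- count_junctions(sam, a)
  expect_equal(cts$R_L, 1)     # rL2 fails the 6-nt anchor
  expect_equal(cts$R_R, 1)
  expect_equal(cts$R_skipped, 2)
  expect_equal(cts$R_tot, 1)
})

test_that("PSI follows 100*Rtot/(Rtot+Rskip) with the <=5-read mask", {
  cts <- data.frame(exon_id = c("a", "b", "c"),
                    R_L = c(10, 0, 3), R_R = c(8, 0, 2),
                    R_skipped = c(2, 10, 1))
  p <- psi(cts)
  expect_equal(p$R_tot, c(8, 0, 2))
  expect_equal(p$PSI, c(80, 0, NA_real_))
})

test_that("inflating one junction side does not move PSI (min rule)", {
  base <- data.frame(exon_id = "a", R_L = 20, R_R = 18, R_skipped = 6)
  alt5 <- transform(base, R_L = 200)   # alternative 5' site inflates R_L only
  expect_equal(psi(base)$PSI, psi(alt5)$PSI)
})

make_pm2 <- function(values, tissues) {
  structure(list(values = values, counts = NULL,
                 tissues = setNames(tissues, colnames(values))),
            class = "psi_matrix")
}

test_that("classification thresholds are inclusive and order-invariant", {
  vals <- rbind(high = c(95, 96, 94), mid = c(50, 55, 45),
                low = c(5, 4, 6), edge_cs = c(90, 90, 90),
                edge_as = c(10, 10, 10), nodata = c(NA, NA, NA))
  colnames(vals) <- paste0("b", 1:3)
  pm <- make_pm2(vals, rep("brain", 3))
  cl <- classify_exons(pm)
  expect_equal(cl$label,
               c("CS", "AS", "not-expressed", "CS", "AS", "not-expressed"))
  expect_equal(cl$note[6], "no-data")

  single <- make_pm2(matrix(70, 1, 1, dimnames = list("x", "b1")), "brain")
  expect_equal(classify_exons(single)$label, "AS")

  perm <- sample(ncol(vals))
  pm2 <- make_pm2(vals[, perm], rep("brain", 3))
  expect_equal(classify_exons(pm2)$label, cl$label)
})

test_that("brain-specific flags use the target median and pooled percentile", {
  samples <- c(paste0("b", 1:4), paste0("m", 1:4), "p1")
  tissues <- c(rep("brain", 4), rep("muscle", 4), "pituitary")
  vals <- rbind(bs = c(30, 35, 28, 32, 5, 4, 6, 5, 90),
                weak = c(20, 22, 18, 21, 5, 4, 6, 5, 5),
                broad = c(40, 45, 42, 41, 30, 35, 28, 33, 30))
  colnames(vals) <- samples
  pm <- make_pm2(vals, tissues)
  bs <- brain_specific(pm)
  expect_equal(bs$brain_specific, c(TRUE, FALSE, FALSE))
  # permutation within tissue groups leaves flags unchanged
  perm <- c(sample(1:4), sample(5:8), 9)
  pm2 <- make_pm2(vals[, perm], tissues[perm])
  expect_equal(brain_specific(pm2)$brain_specific, bs$brain_specific)
  # no non-target samples -> error
  pm3 <- make_pm2(vals[, c(1:4, 9)], tissues[c(1:4, 9)])
  expect_error(brain_specific(pm3), "non-target")
})

test_that("differential inclusion reports |dPSI| > 15 with direction", {
  a <- matrix(c(40, 40, 40), 3, 1,
              dimnames = list(c("up20", "up10", "gone"), "s1"))
  b <- matrix(c(60, 50, NA), 3, 1,
              dimnames = list(c("up20", "up10", "gone"), "s1"))
  d <- differential_inclusion(a, b)
  expect_equal(d$table$exon_id, "up20")
  expect_equal(d$table$delta_psi, 20)
  expect_equal(d$table$direction, "up")
  expect_equal(d$n_excluded, 1)
})

test_that("simulated reads recover PSI within binomial sampling error", {
  sim <- shared_sim()
  rd <- simulate_reads(sim, tempfile("quant"), seed = 17,
                       samples = head(sim$config$samples, 3),
                       depth = 60, write_disc = FALSE, write_fastq = FALSE)
  cts <- lapply(rd$quant_sam, count_junctions, augmented = rd$augmented)
  pm <- psi_matrix(cts, setNames(sim$config$samples$tissue,
                                 sim$config$samples$sample_id))
  rep <- recovery_report(rd$psi_true, pm)
  ok <- !is.na(rep$per_cell$error)
  expect_gt(mean(ok), 0.9)
  # ~50 informative reads -> binomial SE <= ~7.1 PSI; 3 SE covers >= 95%
  expect_lt(abs(rep$summary$bias), 5)
  expect_lt(rep$summary$rmse, 12)
})
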