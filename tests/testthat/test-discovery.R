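make_events <- function(offsets, seqs = "TTT", n = 1, tx = "t1") {
  data.frame(read_id = sprintf("r%d", seq_len(length(offsets) * n)),
             transcript_id = tx,
             insertion_offset = rep(offsets, each = n),
             inserted_seq = rep(seqs, length.out = length(offsets) * n),
             left_flank = 30L, right_flank = 30L, mismatches = 0L,
             stringsAsFactors = FALSE)
}

test_that("insertion extraction applies size, flank and mismatch filters", {
  refs <- c(t1 = 300L)
  recs <- c(
    sam_record("keep", "t1", 1, "30M9I37M", strrep("A", 76), nm = 9),
    sam_record("flank", "t1", 1, "3M9I64M", strrep("A", 76), nm = 9),
    sam_record("toolong", "t1", 1, "20M60I20M", strrep("A", 100), nm = 60),
    sam_record("mm", "t1", 1, "30M9I37M", strrep("A", 76), nm = 12))
  sam <- write_toy_sam(recs, refs)
  ev <- extract_insertions(sam)
  expect_equal(ev$read_id, "keep")
  expect_equal(nchar(ev$inserted_seq), 9)
  expect_equal(ev$left_flank, 30)
  expect_equal(ev$right_flank, 37)
  expect_equal(ev$insertion_offset, 30)
  s <- attr(ev, "summary")
  expect_equal(s$n_fail_flank, 1)
  expect_equal(s$n_fail_len, 1)
  expect_equal(s$n_fail_mismatch, 1)   # NM 12 - 9 inserted = 3 substitutions
})

test_that("malformed CIGAR records are skipped with a warning", {
  sam <- write_toy_sam(c(
    sam_record("ok", "t1", 1, "30M9I37M", strrep("A", 76), nm = 9),
    sam_record("bad", "t1", 1, "3Q9I", strrep("A", 12))), c(t1 = 300L))
  expect_warning(ev <- extract_insertions(sam), "malformed")
  expect_equal(nrow(ev), 1)
})

test_that("boundary grouping keeps exact-offset events with >= 10 reads", {
  model <- toy_model("+")   # boundaries at transcript offsets 50 and 74
  cand <- group_by_boundary(make_events(50, n = 12), model)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$supporting_reads, 12)
  expect_equal(cand$up_exon, "chr1:100-150:+")
  expect_equal(cand$down_exon, "chr1:200-224:+")

  expect_equal(nrow(group_by_boundary(make_events(50, n = 9), model)), 0)
  expect_equal(nrow(group_by_boundary(make_events(55, n = 20), model)), 0)
})

test_that("events on unknown transcripts are skipped with a message", {
  model <- toy_model("+")
  ev <- rbind(make_events(50, n = 12), make_events(50, n = 12, tx = "ghost"))
  expect_message(cand <- group_by_boundary(ev, model), "ghost")
  expect_equal(attr(cand, "n_skipped_events"), 12)
})

intron_fixture <- function(intron_core) {
  # gene: exon (0,10) | intron | exon (10+L, 20+L); intron given explicitly
  L <- nchar(intron_core)
  g <- paste0(fill_seq(10), intron_core, fill_seq(10))
  exons <- data.frame(contig = "chr1", start = c(0L, 10L + L),
                      end = c(10L, 20L + L), strand = "+",
                      gene_id = "g", transcript_id = "t1")
  genome_model(c(chr1 = g), exons)
}

cand_row <- function(model, seq) {
  e <- model$exons
  data.frame(up_exon = e$exon_id[1], down_exon = e$exon_id[2],
             inserted_seq = seq, supporting_reads = 10L,
             transcripts = "t1", stringsAsFactors = FALSE)
}

test_that("intron placement requires exact match with AG]...[GT context", {
  m <- intron_fixture(paste0("GTAAGT", fill_seq(20), "AGTTCGT",
                             fill_seq(20), "AG"))
  res <- locate_in_intron(cand_row(m, "TTC"), m)
  expect_true(res$placed)
  expect_equal(res$n_hits, 1)
  expect_false(res$ambiguous)
  # TTC sits right after "AG" at intron offset 28 -> genomic 10 + 28
  expect_equal(res$start, 38)
  expect_equal(res$end, 41)

  # context AC instead of AG: unplaceable
  m2 <- intron_fixture(paste0("GTAAGT", fill_seq(20), "ACTTCGT",
                              fill_seq(20), "AG"))
  res2 <- locate_in_intron(cand_row(m2, "TTC"), m2)
  expect_false(res2$placed)
  expect_equal(res2$n_hits, 0)
})

test_that("ambiguous placements are seeded-random and reproducible", {
  m <- intron_fixture(paste0("GTAAGT", fill_seq(10), "AGTTCGT",
                             fill_seq(10), "AGTTCGT", fill_seq(10), "AG"))
  r1 <- locate_in_intron(cand_row(m, "TTC"), m, seed = 7)
  r2 <- locate_in_intron(cand_row(m, "TTC"), m, seed = 7)
  expect_equal(r1$n_hits, 2)
  expect_true(r1$ambiguous)
  expect_true(r1$placed)
  expect_identical(r1$start, r2$start)
})

test_that("ambiguity report partitions candidates by length", {
  cand <- data.frame(inserted_seq = c("TTT", "CCC", "GGG", "AAA", "TTTTTT"),
                     ambiguous = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  rep <- ambiguity_report(cand)
  expect_equal(rep$fraction_ambiguous[rep$length == "3"], 0.5)
  expect_equal(rep$n_candidates[rep$length == "overall"], 5)
  expect_equal(sum(rep$n_candidates[rep$length != "overall"]), 5)
  all_unique <- ambiguity_report(data.frame(inserted_seq = c("AAA", "CCC"),
                                            ambiguous = FALSE))
  expect_true(all(all_unique$fraction_ambiguous == 0))
})

make_pm <- function(values, tissues) {
  structure(list(values = values, counts = NULL,
                 tissues = setNames(tissues, colnames(values))),
            class = "psi_matrix")
}

test_that("novel calls require breadth in some tissue and no known overlap", {
  cand <- data.frame(up_exon = "chr1:0-10:+", down_exon = "chr1:100-110:+",
                     inserted_seq = "TTTTTT", supporting_reads = 12L,
                     transcripts = "t1", placed = TRUE, n_hits = 1L,
                     ambiguous = FALSE, exon_id = "chr1:50-56:+",
                     contig = "chr1", start = 50L, end = 56L, strand = "+",
                     stringsAsFactors = FALSE)
  known <- data.frame(contig = "chr2", start = 0L, end = 10L, strand = "+")
  vals <- matrix(NA_real_, 1, 10,
                 dimnames = list("chr1:50-56:+", paste0("s", 1:10)))
  tissues <- rep(c("brain", "muscle"), each = 5)

  v <- vals; v[1, 1] <- 20      # 1 of 5 brain samples (20%) at PSI >= 5
  nov <- call_novel(cand, make_pm(v, tissues), known)
  expect_equal(nov$exon_id, "chr1:50-56:+")
  expect_equal(nov$origin, "novel")

  v2 <- vals; v2[1, c(1, 6)] <- 4   # expressed nowhere above 5 PSI
  expect_equal(nrow(call_novel(cand, make_pm(v2, tissues), known)), 0)

  # 10% of every tissue (1 of 10 overall) fails the per-tissue 15% rule
  v3 <- vals; v3[1, 1] <- 50
  expect_equal(nrow(call_novel(cand, make_pm(v3, tissues), known,
                               min_sample_frac = 0.25)), 0)

  # overlapping a known internal exon: stays annotated, not novel
  known2 <- data.frame(contig = "chr1", start = 52L, end = 60L, strand = "+")
  expect_equal(nrow(call_novel(cand, make_pm(v, tissues), known2)), 0)
})

test_that("discovery filters are monotone and seeded-deterministic", {
  cfg <- sim_config(
    genes = list(sim_gene(17, "AS", novel = TRUE),
                 sim_gene(24, "CS", novel = TRUE),
                 sim_gene(12, "CS")),
    samples = data.frame(sample_id = c("b1", "b2"),
                         tissue = c("brain", "brain")))
  sim <- make_genome(cfg, seed = 31)
  rd <- simulate_reads(sim, tempfile("disc"), seed = 9, write_fastq = FALSE)
  ev <- extract_insertions(unname(rd$disc_sam))
  expect_gt(nrow(ev), 0)
  # monotone in min_flank
  ev_strict <- extract_insertions(unname(rd$disc_sam), min_flank = 20)
  expect_true(all(paste(ev_strict$read_id, ev_strict$insertion_offset) %in%
                    paste(ev$read_id, ev$insertion_offset)))
  # monotone in min_reads
  c10 <- group_by_boundary(ev, sim$model_annot, min_reads = 10)
  c40 <- group_by_boundary(ev, sim$model_annot, min_reads = 40)
  expect_true(all(c40$inserted_seq %in% c10$inserted_seq))
  # byte-identical rerun with the same seed
  a <- discover_candidates(unname(rd$disc_sam), sim$model_annot, seed = 5)
  b <- discover_candidates(unname(rd$disc_sam), sim$model_annot, seed = 5)
  expect_identical(a, b)
  # both planted novel exons are placed at their exact loci
  expect_setequal(a$exon_id[a$placed],
                  sim$truth$micro$exon_id[sim$truth$micro$novel])
})
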