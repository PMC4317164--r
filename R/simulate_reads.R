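#' @rdname simulate
#' @name simulate_reads_module
NULL

# micro-exon truth table of a sim_genome as a micro_exons data.frame
# (the same container discovery / annotation produce).
truth_micro_exons <- function(sim) {
  tm <- sim$truth$micro
  out <- data.frame(exon_id = tm$exon_id, contig = tm$contig,
                    start = tm$start, end = tm$end, strand = tm$strand,
                    length = tm$length,
                    origin = ifelse(tm$novel, "novel", "annotated"),
                    acceptor_dinuc = "AG", donor_dinuc = "GT",
                    canonical = TRUE, transcripts = tm$transcript_id,
                    stringsAsFactors = FALSE)
  class(out) <- c("micro_exons", "data.frame")
  out
}

mutate_bases <- function(seqs, n_err) {
  idx <- which(n_err > 0)
  for (i in idx) {
    rl <- nchar(seqs[i])
    pos <- sample.int(rl, min(n_err[i], rl))
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    }
  }
  seqs
}

# Per-transcript simulation scaffolding shared across samples.
tx_sim_info <- function(sim, aug, tx) {
  model <- sim$model_true
  mes_tx <- mes_of_tx(truth_micro_exons(sim), tx)
  k <- nrow(mes_tx)
  allin <- rep(TRUE, k)
  chain <- iso_chain(model, tx, mes_tx, allin)
  iso_allin <- iso_id_of(tx, allin)
  seq_allin <- aug$isoforms$seq[aug$isoforms$iso_id == iso_allin]
  clusters <- if (k > 0) cluster_micro_exons(mes_tx, 100) else integer(0)
  cl_info <- list()
  for (c in unique(clusters)) {
    members <- which(clusters == c)
    rows <- match(mes_tx$exon_id[members], chain$exon_id)
    cl_info[[as.character(c)]] <- list(
      members = members,
      zs = min(chain$iso_start[rows]), ze = max(chain$iso_end[rows]),
      combos = new.env(parent = emptyenv()))
  }
  list(tx = tx, mes_tx = mes_tx, chain = chain, iso_allin = iso_allin,
       seq_allin = seq_allin, L = nchar(seq_allin), clusters = clusters,
       cl_info = cl_info, model = model)
}

combo_of <- function(info, aug, cl, bits) {
  key <- paste(as.integer(bits), collapse = "")
  env <- cl$combos
  if (!is.null(env[[key]])) return(env[[key]])
  k <- nrow(info$mes_tx)
  v <- rep(TRUE, k); v[cl$members] <- bits
  iso <- iso_id_of(info$tx, v)
  chain <- iso_chain(info$model, info$tx, info$mes_tx, v)
  sq <- aug$isoforms$seq[aug$isoforms$iso_id == iso]
  removed <- sum(info$mes_tx$length[cl$members][!bits])
  env[[key]] <- list(iso = iso, chain = chain, seq = sq,
                     L = nchar(sq), ze2 = cl$ze - removed)
  env[[key]]
}

# CIGAR + reference position of a read [s0, e0) on isoform `chain` against
# the annotated reference chain (named cumulative offsets `ref_cum`,
# lengths `ref_len` by exon_id). Returns NULL when an end lies in an exon
# absent from the reference (cannot anchor).
map_read_to_ref <- function(chain, ref_cum, ref_len, s0, e0) {
  rows <- which(chain$iso_start < e0 & chain$iso_end > s0)
  ids <- chain$exon_id[rows]
  in_ref <- ids %in% names(ref_cum)
  if (!in_ref[1] || !in_ref[length(in_ref)]) return(NULL)
  a <- pmax(s0, chain$iso_start[rows]) - chain$iso_start[rows]
  len <- pmin(e0, chain$iso_end[rows]) - pmax(s0, chain$iso_start[rows])
  pos0 <- ref_cum[[ids[1]]] + a[1]
  ops <- character(0); lens <- integer(0)
  push <- function(op, n) {
    if (n <= 0) return()
    if (length(ops) && ops[length(ops)] == op) {
      lens[length(lens)] <<- lens[length(lens)] + n
    } else { ops <<- c(ops, op); lens <<- c(lens, n) }
  }
  last_ref <- NA_character_
  for (i in seq_along(rows)) {
    if (in_ref[i]) {
      if (!is.na(last_ref)) {
        gap <- ref_cum[[ids[i]]] - (ref_cum[[last_ref]] + ref_len[[last_ref]])
        push("D", gap)
      }
      push("M", len[i])
      last_ref <- ids[i]
    } else push("I", len[i])
  }
  list(pos0 = pos0, cigar = paste0(lens, ops, collapse = ""),
       n_ins = sum(lens[ops == "I"]), n_del = sum(lens[ops == "D"]))
}

sam_header <- function(refs) {
  c("@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(refs), unname(refs)))
}

#' Simulate per-sample reads, alignments and ground truth
#'
#' Draws reads uniformly along isoforms. Near each micro-exon cluster the
#' generating isoform is chosen read-locally: each cluster member is
#' included with probability equal to its true PSI, so the expected fraction
#' of junction-informative reads supporting inclusion equals the true PSI
#' (the quantification target is exact by construction). Two SAM files are
#' written per sample: one against the augmented transcriptome (pure-match
#' alignments, exercising quantification) and one against the annotated
#' transcript references, in which reads containing a novel micro-exon
#' appear as insertion-bearing alignments (exercising discovery).
#'
#' @param sim a \code{sim_genome}.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param samples sample sheet; defaults to the config's.
#' @param depth mean per-transcript coverage; defaults to the config's.
#' @param write_disc,write_fastq emit the discovery SAM / FASTQ (default
#'   TRUE; turn off to speed up quantification-only studies).
#' @return object of class \code{sim_reads}: per-sample file paths
#'   (\code{$quant_sam}, \code{$disc_sam}, \code{$fastq}), the
#'   \code{$augmented} transcriptome used, \code{$psi_true}, the sample
#'   sheet and the true genome.
#' @export
simulate_reads <- function(sim, out_dir, seed = 1,
                           samples = sim$config$samples,
                           depth = sim$config$depth,
                           write_disc = TRUE, write_fastq = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim$config
  rl <- cfg$read_length
  mes <- truth_micro_exons(sim)
  aug <- build_augmented(sim$model_true, mes)
  pt <- psi_true(sim, samples)

  txs_all <- unique(sim$model_true$exons$transcript_id)
  infos <- lapply(txs_all, function(tx) {
    if (tx %in% names(aug$by_tx)) {
      tx_sim_info(sim, aug, tx)
    } else {
      chain <- iso_chain(sim$model_true, tx, mes[0, , drop = FALSE], logical(0))
      sq <- chain_seq(sim$model_true, chain)
      list(tx = tx, mes_tx = mes[0, , drop = FALSE], chain = chain,
           iso_allin = tx, seq_allin = sq, L = nchar(sq),
           clusters = integer(0), cl_info = list(), model = sim$model_true)
    }
  })
  names(infos) <- txs_all

  # reference (annotated transcript) chains for the discovery SAM
  refs <- lapply(txs_all, function(tx) {
    e <- transcript_exons(sim$model_annot, tx)
    len <- e$end - e$start
    list(cum = setNames(cumsum(c(0L, len[-length(len)])), e$exon_id),
         len = setNames(len, e$exon_id), total = sum(len))
  })
  names(refs) <- txs_all

  quant_refs <- setNames(aug$isoforms$length, aug$isoforms$iso_id)
  plain_iso <- setdiff(txs_all, names(aug$by_tx))
  for (tx in plain_iso) quant_refs[infos[[tx]]$iso_allin] <- infos[[tx]]$L
  disc_refs <- setNames(vapply(refs, `[[`, numeric(1), "total"), txs_all)

  files <- list(quant_sam = character(0), disc_sam = character(0),
                fastq = character(0))
  for (j in seq_len(nrow(samples))) {
    smp <- samples$sample_id[j]
    res <- with_seed(derive_seed(seed, 1000 + j), {
      simulate_sample_reads(infos, refs, aug, pt, smp, depth, rl,
                            cfg$error_rate, write_disc)
    })
    qs <- file.path(out_dir, paste0(smp, ".quant.sam"))
    writeLines(c(sam_header(quant_refs), res$quant), qs)
    files$quant_sam[smp] <- qs
    if (write_disc) {
      ds <- file.path(out_dir, paste0(smp, ".disc.sam"))
      writeLines(c(sam_header(disc_refs), res$disc), ds)
      files$disc_sam[smp] <- ds
    }
    if (write_fastq) {
      fq <- file.path(out_dir, paste0(smp, ".fastq"))
      writeLines(res$fastq, fq)
      files$fastq[smp] <- fq
    }
  }
  structure(list(out_dir = out_dir, quant_sam = files$quant_sam,
                 disc_sam = files$disc_sam, fastq = files$fastq,
                 augmented = aug, psi_true = pt, samples = samples,
                 sim = sim),
            class = "sim_reads")
}

simulate_sample_reads <- function(infos, refs, aug, pt, smp, depth, rl,
                                  error_rate, write_disc) {
  quant <- list(); disc <- list(); fastq <- list()
  for (info in infos) {
    if (info$L <= rl) next
    n <- max(1L, round(depth * info$L / rl))
    s <- sample.int(info$L - rl + 1L, n, replace = TRUE) - 1L
    iso <- rep(info$iso_allin, n)
    pos <- s
    seqsrc <- rep(1L, n)            # index into combo seq table
    seq_table <- info$seq_allin
    chain_table <- list(info$chain)
    for (cl in info$cl_info) {
      local <- which(s + rl > cl$zs - 0L & s < cl$ze)
      if (length(local) == 0) next
      m <- length(cl$members)
      p <- pt[info$mes_tx$exon_id[cl$members], smp] / 100
      # enumerate the cluster's local inclusion combinations; a read picks
      # combo z with probability proportional to P(z) * window-width(z), so
      # per-position depth is equal across isoforms and the expected
      # junction-spanning inclusion fraction is exactly the true PSI
      codes <- 0:(2^m - 1)
      lo <- max(0L, cl$zs - rl + 1L)
      combos <- lapply(codes, function(code) {
        bits <- as.logical(bitwAnd(code, 2^(seq_len(m) - 1)) > 0)
        cb <- combo_of(info, aug, cl, bits)
        hi <- min(cb$ze2 - 1L, cb$L - rl)
        w <- max(hi - lo + 1L, 1L)
        pz <- prod(ifelse(bits, p, 1 - p))
        c(list(bits = bits, hi = hi, w = w, pz = pz), cb)
      })
      wts <- vapply(combos, function(cb) cb$pz * cb$w, numeric(1))
      pick <- sample.int(length(combos), length(local), replace = TRUE,
                         prob = wts)
      for (ci in unique(pick)) {
        rows <- local[pick == ci]
        cb <- combos[[ci]]
        if (cb$hi < lo) { s2 <- rep(lo, length(rows)) } else {
          s2 <- lo + sample.int(cb$hi - lo + 1L, length(rows),
                                replace = TRUE) - 1L
        }
        iso[rows] <- cb$iso
        pos[rows] <- s2
        ti <- length(seq_table) + 1L
        seq_table[ti] <- cb$seq
        chain_table[[ti]] <- cb$chain
        seqsrc[rows] <- ti
      }
    }
    reads <- substring(seq_table[seqsrc], pos + 1L, pos + rl)
    n_err <- rbinom(n, rl, error_rate)
    reads <- mutate_bases(reads, n_err)
    qn <- sprintf("%s_%s_r%05d|%s", smp, info$tx, seq_len(n), iso)
    quant[[info$tx]] <- sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                                qn, iso, pos + 1L, rl, reads, n_err)
    fastq[[info$tx]] <- as.vector(rbind(paste0("@", qn), reads, "+",
                                        strrep("I", rl)))
    if (write_disc) {
      rf <- refs[[info$tx]]
      dl <- character(n)
      for (i in seq_len(n)) {
        mp <- map_read_to_ref(chain_table[[seqsrc[i]]], rf$cum, rf$len,
                              pos[i], pos[i] + rl)
        if (is.null(mp)) {
          dl[i] <- sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*", qn[i], reads[i])
        } else {
          dl[i] <- sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                           qn[i], info$tx, mp$pos0 + 1L, mp$cigar, reads[i],
                           n_err[i] + mp$n_ins + mp$n_del)
        }
      }
      disc[[info$tx]] <- dl
    }
  }
  list(quant = unlist(quant, use.names = FALSE),
       disc = unlist(disc, use.names = FALSE),
       fastq = unlist(fastq, use.names = FALSE))
}

#' Compare estimates against simulation truth
#'
#' @param truth_psi true PSI matrix (exon x sample) from \code{psi_true}.
#' @param est_psi estimated matrix (a \code{psi_matrix} or plain matrix).
#' @param called_novel optional character vector of exon_ids called novel by
#'   discovery.
#' @param truth_novel optional character vector of truly novel exon_ids.
#' @return list with \code{$per_cell} (exon, sample, truth, estimate,
#'   error), \code{$summary} (bias, rmse, n_cells, n_missing) and, when
#'   discovery vectors are given, \code{$discovery} (precision, recall).
#' @export
recovery_report <- function(truth_psi, est_psi, called_novel = NULL,
                            truth_novel = NULL) {
  est <- if (inherits(est_psi, "psi_matrix")) est_psi$values else est_psi
  common <- intersect(rownames(truth_psi), rownames(est))
  missing_ids <- setdiff(rownames(truth_psi), rownames(est))
  if (length(common) == 0) stop("no shared exon ids between truth and estimates")
  smp <- intersect(colnames(truth_psi), colnames(est))
  tr <- truth_psi[common, smp, drop = FALSE]
  es <- est[common, smp, drop = FALSE]
  per_cell <- data.frame(exon_id = rep(common, times = length(smp)),
                         sample = rep(smp, each = length(common)),
                         truth = as.vector(tr), estimate = as.vector(es))
  per_cell$error <- per_cell$estimate - per_cell$truth
  ok <- !is.na(per_cell$error)
  out <- list(per_cell = per_cell,
              summary = list(bias = mean(per_cell$error[ok]),
                             rmse = sqrt(mean(per_cell$error[ok]^2)),
                             n_cells = sum(ok), n_missing = sum(!ok),
                             n_unmatched_exons = length(missing_ids)))
  if (!is.null(called_novel) && !is.null(truth_novel)) {
    tp <- length(intersect(called_novel, truth_novel))
    out$discovery <- list(
      precision = if (length(called_novel)) tp / length(called_novel) else NA_real_,
      recall = if (length(truth_novel)) tp / length(truth_novel) else NA_real_)
  }
  out
}
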