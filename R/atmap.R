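#' @title Augmented-transcriptome PSI quantification (ATMap)
#' @description Builds inclusion/exclusion isoforms for every micro-exon
#' (all combinations within 100-nt clusters), counts junction-spanning
#' reads, and derives percent-spliced-in values with the min(R_L, R_R)
#' support rule.
#' @name atmap
NULL

# Single-linkage clustering of micro-exons by genomic gap <= gap.
# `mes` must be sorted by start within one contig/transcript.
cluster_micro_exons <- function(mes, gap = 100) {
  n <- nrow(mes)
  if (n == 0) return(integer(0))
  cl <- integer(n)
  cl[1] <- 1L
  for (i in seq_len(n)[-1]) {
    cl[i] <- if (mes$start[i] - mes$end[i - 1L] <= gap) cl[i - 1L] else cl[i - 1L] + 1L
  }
  cl
}

iso_id_of <- function(tx, incl) {
  paste0(tx, "|", paste(as.integer(incl), collapse = ""))
}

# Exon chain of one isoform in transcript orientation with isoform
# coordinates. micro-exons absent from the annotated chain are spliced in at
# their genomic position.
iso_chain <- function(model, tx, mes_tx, incl) {
  base <- transcript_exons(model, tx)
  base <- base[!(base$exon_id %in% mes_tx$exon_id), , drop = FALSE]
  keep <- mes_tx[incl, , drop = FALSE]
  chain <- data.frame(exon_id = c(base$exon_id, keep$exon_id),
                      contig = c(base$contig, keep$contig),
                      start = c(base$start, keep$start),
                      end = c(base$end, keep$end),
                      strand = base$strand[1], stringsAsFactors = FALSE)
  chain <- chain[order(chain$start), , drop = FALSE]
  if (chain$strand[1] == "-") chain <- chain[rev(seq_len(nrow(chain))), , drop = FALSE]
  chain$len <- chain$end - chain$start
  chain$iso_start <- cumsum(c(0L, chain$len[-nrow(chain)]))
  chain$iso_end <- chain$iso_start + chain$len
  rownames(chain) <- NULL
  chain
}

chain_seq <- function(model, chain) {
  paste(vapply(seq_len(nrow(chain)), function(i) {
    get_seq(model, chain$contig[i], chain$start[i], chain$end[i], chain$strand[i])
  }, character(1)), collapse = "")
}

# Inclusion vectors for one transcript: all-in and all-out backbones plus,
# for each cluster, every local combination with out-of-cluster micro-exons
# included. Bounds the blow-up at sum(2^m_c) + 2 while covering every
# junction a single read can span.
enumerate_inclusions <- function(clusters, max_cluster = 12) {
  k <- length(clusters)
  sizes <- tabulate(clusters)
  if (any(sizes > max_cluster)) {
    stop("micro-exon cluster of size ", max(sizes), " exceeds the cap (",
         max_cluster, "); raise max_cluster to override")
  }
  vecs <- list(rep(TRUE, k), rep(FALSE, k))
  for (c in unique(clusters)) {
    idx <- which(clusters == c)
    m <- length(idx)
    for (code in 0:(2^m - 1)) {
      v <- rep(TRUE, k)
      v[idx] <- as.logical(bitwAnd(code, 2^(seq_len(m) - 1)) > 0)
      vecs[[length(vecs) + 1L]] <- v
    }
  }
  keys <- vapply(vecs, function(v) paste(as.integer(v), collapse = ""), character(1))
  vecs[!duplicated(keys)]
}

# Micro-exons of the table assigned to transcript tx, in genomic order.
mes_of_tx <- function(micro_exons, tx) {
  hit <- vapply(strsplit(micro_exons$transcripts, ","), function(t) tx %in% t,
                logical(1))
  m <- micro_exons[hit, , drop = FALSE]
  m[order(m$start), , drop = FALSE]
}

#' Build the augmented transcriptome
#'
#' For every transcript hosting micro-exons, constructs inclusion/exclusion
#' isoforms: an all-included and an all-excluded backbone, plus every local
#' combination within clusters of micro-exons whose genomic gap is at most
#' \code{cluster_gap} nt (single linkage), with out-of-cluster micro-exons
#' included. Micro-exons not present in the annotated exon chain (novel
#' calls) are spliced in at their genomic position.
#'
#' @param model a \code{genome_model}.
#' @param micro_exons a \code{micro_exons} data.frame with a
#'   \code{transcripts} column naming host transcripts.
#' @param cluster_gap maximum genomic gap (nt) for joint enumeration
#'   (default 100).
#' @param max_cluster hard cap on cluster size (default 12).
#' @return an object of class \code{augmented_transcriptome} with
#'   \code{$isoforms} (iso_id, transcript_id, inclusion, length, seq) and
#'   \code{$junctions} (iso_id, pos, up_exon, down_exon, skipped).
#' @export
build_augmented <- function(model, micro_exons, cluster_gap = 100,
                            max_cluster = 12) {
  txs <- sort(unique(unlist(strsplit(micro_exons$transcripts, ","))))
  isoforms <- list(); junctions <- list()
  by_tx <- list()
  for (tx in txs) {
    mes_tx <- mes_of_tx(micro_exons, tx)
    if (nrow(mes_tx) == 0) next
    by_tx[[tx]] <- mes_tx$exon_id
    clusters <- cluster_micro_exons(mes_tx, cluster_gap)
    vecs <- enumerate_inclusions(clusters, max_cluster)
    for (v in vecs) {
      chain <- iso_chain(model, tx, mes_tx, v)
      iso <- iso_id_of(tx, v)
      sq <- chain_seq(model, chain)
      isoforms[[iso]] <- data.frame(
        iso_id = iso, transcript_id = tx,
        inclusion = paste(as.integer(v), collapse = ""),
        length = nchar(sq), seq = sq, stringsAsFactors = FALSE)
      nj <- nrow(chain) - 1L
      if (nj > 0) {
        up <- chain$exon_id[seq_len(nj)]
        dn <- chain$exon_id[seq_len(nj) + 1L]
        lo <- pmin(chain$end[seq_len(nj)], chain$end[seq_len(nj) + 1L])
        hi <- pmax(chain$start[seq_len(nj)], chain$start[seq_len(nj) + 1L])
        skipped <- vapply(seq_len(nj), function(i) {
          s <- mes_tx$exon_id[mes_tx$start >= lo[i] & mes_tx$end <= hi[i]]
          paste(s, collapse = ",")
        }, character(1))
        junctions[[iso]] <- data.frame(
          iso_id = iso, pos = chain$iso_end[seq_len(nj)],
          up_exon = up, down_exon = dn, skipped = skipped,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(isoforms = do.call(rbind, c(isoforms, list(make.row.names = FALSE))),
                 junctions = do.call(rbind, c(junctions, list(make.row.names = FALSE))),
                 micro_exons = micro_exons, by_tx = by_tx),
            class = "augmented_transcriptome")
}

#' @export
print.augmented_transcriptome <- function(x, ...) {
  cat("augmented_transcriptome:", nrow(x$isoforms), "isoform(s) over",
      length(x$by_tx), "transcript(s),", nrow(x$micro_exons), "micro-exon(s)\n")
  invisible(x)
}

#' Write augmented isoform sequences as FASTA
#' @param augmented an \code{augmented_transcriptome}.
#' @param path output FASTA path.
#' @export
write_augmented_fasta <- function(augmented, path) {
  s <- Biostrings::DNAStringSet(setNames(augmented$isoforms$seq,
                                         augmented$isoforms$iso_id))
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

# Read primary alignments from a SAM/BAM file into a plain data.frame
# (rname, start0, end0, nm_sub = NM minus indel bases).
read_sam_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags, what = c("qname", "seq"),
                                   tag = "NM")
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  cig <- GenomicAlignments::cigar(ga)
  ins <- vapply(GenomicAlignments::explodeCigarOpLengths(cig, ops = "I"), sum, numeric(1))
  del <- vapply(GenomicAlignments::explodeCigarOpLengths(cig, ops = "D"), sum, numeric(1))
  nm <- S4Vectors::mcols(ga)$NM
  nm_sub <- ifelse(is.na(nm), 0L, pmax(0L, nm - ins - del))
  data.frame(qname = S4Vectors::mcols(ga)$qname,
             rname = as.character(GenomicAlignments::seqnames(ga)),
             start0 = GenomicAlignments::start(ga) - 1L,
             end0 = GenomicAlignments::end(ga),
             cigar = cig,
             seq = as.character(S4Vectors::mcols(ga)$seq),
             nm_sub = nm_sub,
             stringsAsFactors = FALSE)
}

#' Count junction-spanning reads per micro-exon
#'
#' A read spans a junction when its alignment covers at least
#' \code{min_anchor} nt on both sides of the junction position in its
#' isoform. R_L and R_R count reads over the (upstream|micro) and
#' (micro|downstream) junctions; R_skipped counts reads over junctions that
#' splice directly past the micro-exon. R_tot = min(R_L, R_R), which guards
#' the estimate against alternative 5'/3' splice sites inflating one side.
#'
#' @param reads a SAM/BAM path or a data.frame from
#'   \code{read_sam_alignments}.
#' @param augmented an \code{augmented_transcriptome}.
#' @param min_anchor minimum nt on each side of the junction (default 6).
#' @param max_mismatch maximum substitutions per read (NM minus indel bases;
#'   default 2).
#' @return data.frame (exon_id, R_L, R_R, R_skipped, R_tot), one row per
#'   micro-exon in \code{augmented}.
#' @export
count_junctions <- function(reads, augmented, min_anchor = 6, max_mismatch = 2) {
  if (is.character(reads)) reads <- read_sam_alignments(reads)
  jt <- augmented$junctions
  mes <- augmented$micro_exons$exon_id
  out <- data.frame(exon_id = mes, R_L = 0L, R_R = 0L, R_skipped = 0L,
                    stringsAsFactors = FALSE)
  if (!is.null(reads) && nrow(reads) > 0) {
    reads <- reads[reads$nm_sub <= max_mismatch, , drop = FALSE]
  }
  if (!is.null(reads) && nrow(reads) > 0 && nrow(jt) > 0) {
    # expand: for each junction, count reads of that isoform spanning it
    jsplit <- split(jt, jt$iso_id)
    rsplit <- split(reads, reads$rname)
    tallies <- list()
    for (iso in names(jsplit)) {
      r <- rsplit[[iso]]
      if (is.null(r)) next
      j <- jsplit[[iso]]
      for (i in seq_len(nrow(j))) {
        n <- sum(j$pos[i] - r$start0 >= min_anchor & r$end0 - j$pos[i] >= min_anchor)
        if (n > 0) {
          tallies[[length(tallies) + 1L]] <-
            data.frame(up = j$up_exon[i], dn = j$down_exon[i],
                       skipped = j$skipped[i], n = n, stringsAsFactors = FALSE)
        }
      }
    }
    if (length(tallies) > 0) {
      tl <- do.call(rbind, tallies)
      for (k in seq_along(mes)) {
        me <- mes[k]
        out$R_L[k] <- sum(tl$n[tl$dn == me])
        out$R_R[k] <- sum(tl$n[tl$up == me])
        sk <- vapply(strsplit(tl$skipped, ","), function(s) me %in% s, logical(1))
        out$R_skipped[k] <- sum(tl$n[sk])
      }
    }
  }
  out$R_tot <- pmin(out$R_L, out$R_R)
  out
}

#' Percent spliced-in from junction counts
#'
#' PSI = 100 * R_tot / (R_tot + R_skipped) with R_tot = min(R_L, R_R),
#' reported as missing (NA) when fewer than \code{min_informative} reads
#' inform the estimate (R_tot + R_skipped).
#'
#' @param counts data.frame from \code{count_junctions} (or any frame with
#'   R_L, R_R, R_skipped columns).
#' @param min_informative minimum informative reads (default 6, i.e. "<= 5
#'   reads" is masked).
#' @return the input with R_tot and PSI columns added (PSI NA when masked).
#' @export
psi <- function(counts, min_informative = 6) {
  counts$R_tot <- pmin(counts$R_L, counts$R_R)
  inform <- counts$R_tot + counts$R_skipped
  counts$PSI <- ifelse(inform >= min_informative,
                       100 * counts$R_tot / inform, NA_real_)
  counts
}

#' Assemble a PSI matrix over samples
#'
#' @param counts_by_sample named list (sample id -> count frame from
#'   \code{count_junctions}).
#' @param sample_tissues named character vector, sample id -> tissue.
#' @param min_informative passed to \code{\link{psi}}.
#' @return object of class \code{psi_matrix}: \code{$values} (exon x sample,
#'   NA where masked), \code{$counts}, \code{$tissues}.
#' @export
psi_matrix <- function(counts_by_sample, sample_tissues, min_informative = 6) {
  stopifnot(length(counts_by_sample) > 0)
  samples <- names(counts_by_sample)
  exons <- counts_by_sample[[1]]$exon_id
  vals <- sapply(samples, function(s) {
    p <- psi(counts_by_sample[[s]], min_informative)
    p$PSI[match(exons, p$exon_id)]
  })
  vals <- matrix(vals, nrow = length(exons),
                 dimnames = list(exons, samples))
  structure(list(values = vals, counts = counts_by_sample,
                 tissues = sample_tissues[samples]),
            class = "psi_matrix")
}

#' @export
print.psi_matrix <- function(x, ...) {
  cat("psi_matrix:", nrow(x$values), "exon(s) x", ncol(x$values),
      "sample(s);", round(100 * mean(is.na(x$values)), 1), "% masked\n")
  invisible(x)
}

tissue_cols <- function(pm, tissue) {
  which(pm$tissues == tissue)
}

#' Classify exons as constitutive / alternative / not expressed
#'
#' Uses the median PSI over non-missing samples of one tissue: median >=
#' \code{cs_min} is constitutive (CS), median in [\code{as_min},
#' \code{cs_min}) is alternative (AS), below \code{as_min} not expressed.
#'
#' @param pm a \code{psi_matrix}.
#' @param tissue tissue whose samples are used (default "brain").
#' @param cs_min,as_min class thresholds in PSI percent (defaults 90 and 10).
#' @return data.frame (exon_id, median_psi, n_informative, label, note);
#'   label in {CS, AS, not-expressed}; note "no-data" when every sample is
#'   masked.
#' @export
classify_exons <- function(pm, tissue = "brain", cs_min = 90, as_min = 10) {
  cols <- tissue_cols(pm, tissue)
  if (length(cols) == 0) stop("no samples for tissue: ", tissue)
  v <- pm$values[, cols, drop = FALSE]
  med <- apply(v, 1, function(x) if (all(is.na(x))) NA_real_ else median(x, na.rm = TRUE))
  n_inf <- rowSums(!is.na(v))
  label <- ifelse(is.na(med), "not-expressed",
                  ifelse(med >= cs_min, "CS",
                         ifelse(med >= as_min, "AS", "not-expressed")))
  data.frame(exon_id = rownames(pm$values), median_psi = unname(med),
             n_informative = unname(n_inf), label = label,
             note = ifelse(is.na(med), "no-data", ""),
             stringsAsFactors = FALSE)
}

#' Flag brain-specific exons
#'
#' An exon is brain-specific when its median PSI over target-tissue samples
#' is at least \code{target_median_min} and the \code{other_pctl}-th
#' percentile of PSI over all pooled non-target samples (excluding
#' \code{exclude} tissues) is at most \code{other_max}.
#'
#' @param pm a \code{psi_matrix}.
#' @param target target tissue (default "brain").
#' @param exclude tissues dropped from the non-target pool (default
#'   "pituitary").
#' @param target_median_min,other_pctl,other_max thresholds (defaults 25,
#'   80, 10).
#' @return data.frame (exon_id, target_median, other_pctl_value,
#'   brain_specific).
#' @export
brain_specific <- function(pm, target = "brain", exclude = "pituitary",
                           target_median_min = 25, other_pctl = 80,
                           other_max = 10) {
  tcols <- tissue_cols(pm, target)
  ocols <- which(!(pm$tissues %in% c(target, exclude)))
  if (length(ocols) == 0) stop("no non-target samples available")
  tmed <- apply(pm$values[, tcols, drop = FALSE], 1, function(x)
    if (all(is.na(x))) NA_real_ else median(x, na.rm = TRUE))
  opct <- apply(pm$values[, ocols, drop = FALSE], 1, function(x)
    if (all(is.na(x))) NA_real_ else quantile(x, other_pctl / 100, na.rm = TRUE))
  flag <- !is.na(tmed) & !is.na(opct) & tmed >= target_median_min &
    opct <= other_max
  data.frame(exon_id = rownames(pm$values), target_median = unname(tmed),
             other_pctl_value = unname(opct), brain_specific = unname(flag),
             stringsAsFactors = FALSE)
}

#' Differential micro-exon inclusion between two conditions
#'
#' Summarizes each condition by the per-exon median PSI over non-missing
#' samples and reports exons with |median_B - median_A| strictly greater
#' than \code{min_delta}.
#'
#' @param pm_a,pm_b \code{psi_matrix} objects (or plain matrices) sharing
#'   exon ids.
#' @param min_delta reporting threshold in PSI percent (default 15).
#' @return list with \code{$table} (exon_id, psi_a, psi_b, delta_psi,
#'   direction) and \code{$n_excluded} (exons missing in either condition).
#' @export
differential_inclusion <- function(pm_a, pm_b, min_delta = 15) {
  va <- if (inherits(pm_a, "psi_matrix")) pm_a$values else pm_a
  vb <- if (inherits(pm_b, "psi_matrix")) pm_b$values else pm_b
  common <- intersect(rownames(va), rownames(vb))
  meda <- apply(va[common, , drop = FALSE], 1, median, na.rm = TRUE)
  medb <- apply(vb[common, , drop = FALSE], 1, median, na.rm = TRUE)
  ok <- !is.na(meda) & !is.na(medb)
  delta <- medb[ok] - meda[ok]
  hit <- abs(delta) > min_delta
  tab <- data.frame(exon_id = common[ok][hit], psi_a = unname(meda[ok][hit]),
                    psi_b = unname(medb[ok][hit]), delta_psi = unname(delta[hit]),
                    direction = ifelse(delta[hit] > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-abs(tab$delta_psi)), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, n_excluded = sum(!ok) + length(setdiff(rownames(va), common)) +
         length(setdiff(rownames(vb), common)))
}

#' Write a PSI matrix as TSV (exons x samples, NA for missing)
#' @param pm a \code{psi_matrix}.
#' @param path output path.
#' @export
write_psi_tsv <- function(pm, path) {
  df <- data.frame(exon_id = rownames(pm$values), pm$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
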