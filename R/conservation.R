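#' @title Conservation analytics
#' @description Bootstrap conservation/coverage profiles around exons,
#' per-exon mean-score classification, alignment-entropy conserved 6-mer
#' scanning with per-class enrichment, and flank percent identity.
#' @name conservation
NULL

#' Per-base score track
#'
#' @param scores named list of numeric vectors (one per contig; NA where
#'   the score is missing).
#' @return object of class \code{score_track}.
#' @export
score_track <- function(scores) {
  stopifnot(is.list(scores), !is.null(names(scores)))
  structure(list(scores = scores), class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat("score_track:", length(x$scores), "contig(s),",
      sum(lengths(x$scores)), "positions\n")
  invisible(x)
}

#' Read a score/coverage track from wiggle or bedGraph
#'
#' @param path file (fixed/variable-step wiggle or bedGraph; format from
#'   extension).
#' @param contig_lengths named integer vector of contig lengths (positions
#'   not covered by the file are NA).
#' @return a \code{score_track}.
#' @export
read_score_track <- function(path, contig_lengths) {
  fmt <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE)) "bedGraph" else "wig"
  gr <- rtracklayer::import(path, format = fmt)
  scores <- lapply(contig_lengths, function(L) rep(NA_real_, L))
  df <- as.data.frame(gr)
  for (ctg in intersect(unique(as.character(df$seqnames)), names(scores))) {
    d <- df[df$seqnames == ctg, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      scores[[ctg]][d$start[i]:d$end[i]] <- d$score[i]
    }
  }
  score_track(scores)
}

#' Write a score track as bedGraph
#' @param track a \code{score_track}.
#' @param path output path.
#' @export
write_score_track <- function(track, path) {
  lines <- unlist(lapply(names(track$scores), function(ctg) {
    v <- track$scores[[ctg]]
    ok <- which(!is.na(v))
    if (length(ok) == 0) return(character(0))
    brk <- c(0L, which(diff(ok) != 1 | diff(v[ok]) != 0), length(ok))
    vapply(seq_len(length(brk) - 1L), function(i) {
      idx <- ok[(brk[i] + 1L):brk[i + 1L]]
      sprintf("%s\t%d\t%d\t%g", ctg, idx[1] - 1L, idx[length(idx)], v[idx[1]])
    }, character(1))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Bootstrap mean profile with quantile confidence band
#'
#' Per-position mean over a set of equal-length score vectors, with lower
#' and upper bounds from B bootstrap resamples (drawing |S| vectors with
#' replacement and recording each resample's per-position mean; bounds are
#' the requested quantiles of those B means, type-7 interpolation).
#'
#' @param score_vectors numeric matrix (one row per exon/vector) or list of
#'   equal-length vectors.
#' @param B bootstrap replicates (default 1000).
#' @param quantiles lower/upper quantiles in percent (default c(5, 95)).
#' @param seed integer seed (resampling is deterministic given the seed).
#' @param positions relative positions (default centered, e.g. -150..149
#'   for a 300-nt window).
#' @return object of class \code{profile_ci}: data.frame (position, mean,
#'   lo, hi) with attributes B, n_vectors, quantiles.
#' @export
bootstrap_profile <- function(score_vectors, B = 1000, quantiles = c(5, 95),
                              seed = 1, positions = NULL) {
  m <- if (is.list(score_vectors)) do.call(rbind, score_vectors) else
    as.matrix(score_vectors)
  n <- nrow(m); L <- ncol(m)
  if (n == 0) stop("empty score-vector set")
  if (is.null(positions)) positions <- seq_len(L) - (L %/% 2L) - 1L
  mu <- colMeans(m, na.rm = TRUE)
  boots <- with_seed(derive_seed(seed, 97), {
    t(vapply(seq_len(B), function(b) {
      colMeans(m[sample.int(n, n, replace = TRUE), , drop = FALSE],
               na.rm = TRUE)
    }, numeric(L)))
  })
  lo <- apply(boots, 2, quantile, probs = quantiles[1] / 100, na.rm = TRUE,
              type = 7)
  hi <- apply(boots, 2, quantile, probs = quantiles[2] / 100, na.rm = TRUE,
              type = 7)
  out <- data.frame(position = positions, mean = mu, lo = lo, hi = hi)
  attr(out, "B") <- B
  attr(out, "n_vectors") <- n
  attr(out, "quantiles") <- quantiles
  class(out) <- c("profile_ci", "data.frame")
  out
}

#' Classify exons by mean conservation score
#'
#' @param exons frame with exon_id (and optionally label).
#' @param track a \code{score_track} with values in [0, 1].
#' @param high,low cutoffs for the reported tail fractions (defaults 0.8
#'   and 0.2).
#' @param max_missing exon dropped when more than this fraction of its
#'   bases lack a score (default 0.5).
#' @return list with \code{$per_exon} (exon_id, mean_score, frac_missing,
#'   dropped) and \code{$fractions} (label, n, frac_high, frac_low).
#' @export
mean_score_classify <- function(exons, track, high = 0.8, low = 0.2,
                                max_missing = 0.5) {
  n <- nrow(exons)
  ms <- rep(NA_real_, n); fm <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    e <- parse_exon_id(exons$exon_id[i])
    v <- track$scores[[e$contig]][(e$start + 1L):e$end]
    fm[i] <- mean(is.na(v))
    if (fm[i] <= max_missing) ms[i] <- mean(v, na.rm = TRUE)
  }
  per_exon <- data.frame(exon_id = exons$exon_id,
                         label = if ("label" %in% names(exons)) exons$label else "all",
                         mean_score = ms, frac_missing = fm,
                         dropped = is.na(ms), stringsAsFactors = FALSE)
  fractions <- do.call(rbind, lapply(split(per_exon, per_exon$label), function(d) {
    ok <- !d$dropped
    data.frame(label = d$label[1], n = sum(ok),
               frac_high = mean(d$mean_score[ok] >= high),
               frac_low = mean(d$mean_score[ok] <= low),
               stringsAsFactors = FALSE)
  }))
  rownames(fractions) <- NULL
  list(per_exon = per_exon, fractions = fractions)
}

#' Multi-species alignment block around an exon
#'
#' @param seqs named character vector of aligned sequences (gaps "-"), all
#'   the same length, including the reference species row.
#' @param region_id identifier of the exon/region the block covers.
#' @param ref name of the reference row (default "human").
#' @param flank5,flank3 number of reference (ungapped) nt labelled as 5'
#'   and 3' intronic; remaining reference positions are exonic.
#' @return object of class \code{msa_block} with per-column region labels.
#' @export
msa_block <- function(seqs, region_id, ref = "human", flank5 = 250,
                      flank3 = 250) {
  stopifnot(length(seqs) >= 2, length(unique(nchar(seqs))) == 1,
            ref %in% names(seqs))
  chars <- strsplit(seqs[[ref]], "")[[1]]
  rp <- cumsum(chars != "-")
  N <- rp[length(rp)]
  region <- ifelse(pmax(rp, 1L) <= flank5, "5-intron",
                   ifelse(pmax(rp, 1L) > N - flank3, "3-intron", "exon"))
  structure(list(region_id = region_id, seqs = seqs, ref = ref,
                 regions = region),
            class = "msa_block")
}

#' Write MSA blocks as multi-FASTA (headers "species|region-id")
#' @param blocks list of \code{msa_block}.
#' @param path output path.
#' @export
write_msa_fasta <- function(blocks, path) {
  lines <- unlist(lapply(blocks, function(b) {
    as.vector(rbind(sprintf(">%s|%s", names(b$seqs), b$region_id),
                    unname(b$seqs)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read MSA blocks from multi-FASTA with "species|region-id" headers
#' @param path input path.
#' @param ref reference species name (default "human").
#' @param flank5,flank3 intronic reference-nt counts used to label columns.
#' @return named list of \code{msa_block} (by region-id).
#' @export
read_msa_fasta <- function(path, ref = "human", flank5 = 250, flank3 = 250) {
  fa <- Biostrings::readBStringSet(path)
  parts <- strsplit(names(fa), "|", fixed = TRUE)
  species <- vapply(parts, `[`, character(1), 1)
  region <- vapply(parts, function(p) paste(p[-1], collapse = "|"), character(1))
  out <- lapply(unique(region), function(r) {
    sel <- region == r
    msa_block(setNames(as.character(fa[sel]), species[sel]), r, ref = ref,
              flank5 = flank5, flank3 = flank3)
  })
  setNames(out, unique(region))
}

# Per-column entropy (natural log by default) and gap flags of a character
# matrix (rows = species).
column_entropy <- function(mat, base = exp(1)) {
  vapply(seq_len(ncol(mat)), function(j) {
    f <- table(mat[, j]) / nrow(mat)
    -sum(f * log(f)) / log(base)
  }, numeric(1))
}

#' Entropy of a k-column alignment window
#'
#' Sum over the k columns of -sum_a f_a log f_a, where f_a is the relative
#' frequency of base a in the column over all rows (natural log by
#' default). Windows containing any gap are excluded and return NA.
#'
#' @param cols character matrix (rows species, k columns) or character
#'   vector of aligned k-mers (one per species).
#' @param base log base (default e; the conventional threshold of 1.0 is
#'   stated in this base).
#' @return entropy >= 0, or NA for gapped windows.
#' @export
entropy_window <- function(cols, base = exp(1)) {
  if (is.null(dim(cols))) cols <- do.call(rbind, strsplit(cols, ""))
  if (any(cols == "-")) return(NA_real_)
  sum(column_entropy(cols, base))
}

#' Scan an MSA block for conserved k-mers
#'
#' Slides a k-column window (step 1); gapless windows with entropy strictly
#' below \code{max_entropy} are reported with the reference row's k-mer and
#' the region label of the window start.
#'
#' @param block an \code{msa_block} (reference row required).
#' @param k window size (default 6).
#' @param max_entropy conservation threshold (default 1.0, natural log).
#' @param base log base (default e).
#' @return data.frame (region_id, region, position, kmer, entropy).
#' @export
conserved_kmer_scan <- function(block, k = 6, max_entropy = 1.0,
                                base = exp(1)) {
  if (!(block$ref %in% names(block$seqs))) {
    stop("reference row missing from MSA block: ", block$ref)
  }
  mat <- do.call(rbind, strsplit(unname(block$seqs), ""))
  L <- ncol(mat)
  empty <- data.frame(region_id = character(0), region = character(0),
                      position = integer(0), kmer = character(0),
                      entropy = numeric(0), stringsAsFactors = FALSE)
  if (L < k) return(empty)
  gapped <- apply(mat == "-", 2, any)
  ent <- numeric(L)
  ent[!gapped] <- column_entropy(mat[, !gapped, drop = FALSE], base)
  cs_e <- cumsum(c(0, ent))
  cs_g <- cumsum(c(0, as.integer(gapped)))
  starts <- seq_len(L - k + 1L)
  wg <- cs_g[starts + k] - cs_g[starts]
  we <- cs_e[starts + k] - cs_e[starts]
  keep <- wg == 0 & we < max_entropy
  if (!any(keep)) return(empty)
  refseq <- block$seqs[[block$ref]]
  data.frame(region_id = block$region_id,
             region = block$regions[starts[keep]],
             position = starts[keep],
             kmer = substring(refseq, starts[keep], starts[keep] + k - 1L),
             entropy = we[keep], stringsAsFactors = FALSE)
}

#' Mean occurrence of conserved k-mers per exon, by class and region
#'
#' @param scans named list (region-id/exon-id -> scan frame from
#'   \code{\link{conserved_kmer_scan}}); exons with zero conserved windows
#'   must still be present (empty frame) to enter the denominator.
#' @param labels named character vector region-id -> class label.
#' @return data.frame (label, region, kmer, mean_per_exon, n_exons), sorted
#'   by decreasing mean within class/region.
#' @export
conserved_kmer_enrichment <- function(scans, labels) {
  rows <- list()
  for (lab in unique(labels)) {
    ids <- names(labels)[labels == lab]
    n_ex <- length(ids)
    sc <- do.call(rbind, scans[ids])
    if (is.null(sc) || nrow(sc) == 0) next
    for (reg in unique(sc$region)) {
      tab <- table(sc$kmer[sc$region == reg])
      rows[[length(rows) + 1L]] <- data.frame(
        label = lab, region = reg, kmer = names(tab),
        mean_per_exon = as.numeric(tab) / n_ex, n_exons = n_ex,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(label = character(0), region = character(0),
                      kmer = character(0), mean_per_exon = numeric(0),
                      n_exons = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$label, out$region, -out$mean_per_exon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percent identity of a pairwise alignment region
#'
#' 100 x matching columns / total columns within the region; columns where
#' either row has a gap count as mismatches.
#'
#' @param x,y aligned sequences of equal length (gaps "-").
#' @param regions optional per-column region labels.
#' @param region optional region to restrict to (requires \code{regions});
#'   NA is returned when the region has no columns.
#' @return percent identity in [0, 100].
#' @export
percent_identity <- function(x, y, regions = NULL, region = NULL) {
  a <- strsplit(x, "")[[1]]; b <- strsplit(y, "")[[1]]
  stopifnot(length(a) == length(b))
  keep <- rep(TRUE, length(a))
  if (!is.null(region)) {
    stopifnot(!is.null(regions), length(regions) == length(a))
    keep <- regions == region
    if (!any(keep)) return(NA_real_)
  }
  100 * sum(a[keep] == b[keep] & a[keep] != "-") / sum(keep)
}

#' Coverage/conservation metagene around exon classes
#'
#' Each exon contributes the score vector of a fixed window centered on its
#' midpoint (minus-strand exons flipped so positions are
#' transcript-oriented); per-class mean profiles with bootstrap confidence
#' bands are returned. Multiple replicate tracks are averaged position-wise
#' first.
#'
#' @param track a \code{score_track} or list of replicate tracks.
#' @param exons frame with exon_id and label columns.
#' @param window window width in nt (default 300).
#' @param B,quantiles,seed passed to \code{\link{bootstrap_profile}}.
#' @return named list (label -> \code{profile_ci}); empty classes yield a
#'   warning and are omitted.
#' @export
coverage_metagene <- function(track, exons, window = 300, B = 1000,
                              quantiles = c(5, 95), seed = 1) {
  if (!inherits(track, "score_track")) {
    stopifnot(length(track) >= 1)
    merged <- track[[1]]$scores
    if (length(track) > 1) {
      for (ctg in names(merged)) {
        m <- rowMeans(do.call(cbind, lapply(track, function(t)
          t$scores[[ctg]])), na.rm = TRUE)
        merged[[ctg]] <- m
      }
    }
    track <- score_track(merged)
  }
  half <- window %/% 2L
  label <- if ("label" %in% names(exons)) exons$label else rep("all", nrow(exons))
  out <- list()
  for (lab in unique(label)) {
    sel <- which(label == lab)
    if (length(sel) == 0) next
    vecs <- matrix(NA_real_, length(sel), window)
    for (r in seq_along(sel)) {
      e <- parse_exon_id(exons$exon_id[sel[r]])
      ctr <- (e$start + e$end) %/% 2L
      idx <- (ctr - half):(ctr + window - half - 1L)
      v <- rep(NA_real_, window)
      ok <- idx >= 0 & idx < length(track$scores[[e$contig]])
      v[ok] <- track$scores[[e$contig]][idx[ok] + 1L]
      if (e$strand == "-") v <- rev(v)
      vecs[r, ] <- v
    }
    out[[lab]] <- bootstrap_profile(vecs, B = B, quantiles = quantiles,
                                    seed = seed,
                                    positions = seq_len(window) - half - 1L)
  }
  if (length(out) == 0) warning("no exons supplied; empty metagene")
  out
}

#' Write a profile with confidence band as TSV
#' @param profile a \code{profile_ci}.
#' @param path output path.
#' @export
write_profile_tsv <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
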