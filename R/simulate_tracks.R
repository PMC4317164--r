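#' @rdname simulate
#' @name simulate_tracks
NULL

# Genomic interval [gs, ge) of a planted motif given its flank-relative
# position (see make_genome: rel_pos is the 0-based offset of the motif
# start from the exon end for "down" flanks, and the negative offset from
# the exon start for "up" flanks, both in sense orientation).
motif_genomic <- function(me, flank, rel_pos, width = 6L) {
  if (flank == "down") {
    if (me$strand == "+") {
      gs <- me$end + rel_pos
    } else {
      gs <- me$start - rel_pos - width
    }
  } else {
    p <- -rel_pos                               # nt before exon start
    if (me$strand == "+") {
      gs <- me$start - p
    } else {
      gs <- me$end + p - width
    }
  }
  c(gs, gs + width)
}

#' Simulate multi-species alignment blocks around planted micro-exons
#'
#' Star phylogeny: each non-reference species substitutes bases
#' independently at \code{bg_sub} per site, reduced to \code{cons_sub}
#' inside conserved windows (the exon body and every planted motif). No
#' indels, so all windows are gapless.
#'
#' @param sim a \code{sim_genome}.
#' @param flank intronic flank width per side (default 250, clipped at
#'   neighboring exons).
#' @param species non-reference species names.
#' @param bg_sub,cons_sub per-site substitution probabilities outside /
#'   inside conserved windows.
#' @param seed integer seed.
#' @return named list of \code{msa_block} keyed by micro-exon id.
#' @export
make_msa_blocks <- function(sim, flank = 250,
                            species = c("macaque", "mouse", "cattle", "dog"),
                            bg_sub = 0.30, cons_sub = 0.02, seed = 1) {
  with_seed(derive_seed(seed, 11), {
    tm <- sim$truth$micro
    model <- sim$model_true
    out <- list()
    for (i in seq_len(nrow(tm))) {
      id <- tm$exon_id[i]
      fl <- flanking_introns(id, model)
      f5 <- min(flank, fl$upstream_length)
      f3 <- min(flank, fl$downstream_length)
      up <- substr(fl$upstream_seq, fl$upstream_length - f5 + 1L,
                   fl$upstream_length)
      dn <- substr(fl$downstream_seq, 1L, f3)
      ex <- get_seq(model, tm$contig[i], tm$start[i], tm$end[i], tm$strand[i])
      ref <- paste0(up, ex, dn)
      L <- nchar(ref)
      conserved <- logical(L)
      conserved[(f5 + 1L):(f5 + nchar(ex))] <- TRUE
      mo <- sim$truth$motifs[sim$truth$motifs$exon_id == id, , drop = FALSE]
      for (j in seq_len(nrow(mo))) {
        if (mo$flank[j] == "down") {
          a <- f5 + nchar(ex) + mo$rel_pos[j] + 1L
        } else {
          a <- f5 + mo$rel_pos[j] + 1L
        }
        w <- if (mo$motif[j] == "U2AF2") nchar(sim$config$u2af2_tract) else 6L
        b <- min(L, a + w - 1L)
        if (a >= 1 && a <= L) conserved[a:b] <- TRUE
      }
      chars <- strsplit(ref, "")[[1]]
      rate <- ifelse(conserved, cons_sub, bg_sub)
      seqs <- c(setNames(ref, "human"),
                vapply(species, function(sp) {
                  mut <- runif(L) < rate
                  s <- chars
                  if (any(mut)) {
                    s[mut] <- vapply(chars[mut], function(o)
                      sample(setdiff(c("A", "C", "G", "T"), o), 1), character(1))
                  }
                  paste(s, collapse = "")
                }, character(1)))
      out[[id]] <- msa_block(seqs, id, ref = "human", flank5 = f5,
                             flank3 = f3)
    }
    out
  })
}

#' Simulate a conservation-style score track
#'
#' Smoothed indicator of the planted conserved regions (micro-exon bodies
#' and planted motifs) plus Gaussian noise, clipped to [0, 1] — a stand-in
#' with the statistical shape of a per-base conservation probability track.
#'
#' @param sim a \code{sim_genome}.
#' @param seed integer seed.
#' @param base,high background and conserved levels (defaults 0.08, 0.95).
#' @param noise_sd Gaussian noise sd (default 0.04).
#' @param smooth moving-average window (odd; default 11).
#' @return a \code{score_track} over the simulated contigs.
#' @export
make_score_track <- function(sim, seed = 1, base = 0.08, high = 0.95,
                             noise_sd = 0.04, smooth = 11) {
  with_seed(derive_seed(seed, 23), {
    model <- sim$model_true
    tm <- sim$truth$micro
    mo <- sim$truth$motifs
    scores <- lapply(model$contigs, function(s) rep(base, nchar(s)))
    mark <- function(ctg, gs, ge, level) {
      gs <- max(0L, gs); ge <- min(length(scores[[ctg]]), ge)
      if (ge > gs) scores[[ctg]][(gs + 1L):ge] <<- level
    }
    for (i in seq_len(nrow(tm))) {
      mark(tm$contig[i], tm$start[i], tm$end[i], high)
    }
    for (j in seq_len(nrow(mo))) {
      me <- tm[tm$exon_id == mo$exon_id[j], , drop = FALSE]
      if (nrow(me) == 0) next
      w <- if (mo$motif[j] == "U2AF2") nchar(sim$config$u2af2_tract) else 6L
      g <- motif_genomic(me[1, ], mo$flank[j], mo$rel_pos[j], w)
      mark(me$contig[1], g[1], g[2], high)
    }
    kern <- rep(1 / smooth, smooth)
    scores <- lapply(scores, function(v) {
      sm <- stats::filter(v, kern, sides = 2)
      sm[is.na(sm)] <- v[is.na(sm)]
      pmin(1, pmax(0, as.numeric(sm) + stats::rnorm(length(v), 0, noise_sd)))
    })
    score_track(scores)
  })
}

#' Simulate a CLIP-style coverage track
#'
#' Uniform background coverage with triangular peaks centered on the
#' planted downstream TGCATG sites — mimicking protein-binding read
#' pile-ups in the 3' intronic flanks of alternative micro-exons.
#'
#' @param sim a \code{sim_genome}.
#' @param seed integer seed.
#' @param background baseline coverage (default 1).
#' @param peak peak height added at the motif center (default 6).
#' @param width peak half-width in nt (default 30).
#' @return a \code{score_track} of per-base coverage.
#' @export
make_coverage_track <- function(sim, seed = 1, background = 1, peak = 6,
                                width = 30) {
  with_seed(derive_seed(seed, 31), {
    model <- sim$model_true
    tm <- sim$truth$micro
    mo <- sim$truth$motifs
    scores <- lapply(model$contigs, function(s)
      background + stats::rpois(nchar(s), 0.2))
    shape <- peak * (1 - abs(seq(-width, width)) / (width + 1))
    for (j in seq_len(nrow(mo))) {
      if (mo$motif[j] != "TGCATG" || mo$flank[j] != "down") next
      me <- tm[tm$exon_id == mo$exon_id[j], , drop = FALSE]
      if (nrow(me) == 0) next
      g <- motif_genomic(me[1, ], mo$flank[j], mo$rel_pos[j])
      ctr <- (g[1] + g[2]) %/% 2L
      idx <- (ctr - width):(ctr + width)
      ok <- idx >= 0 & idx < length(scores[[me$contig[1]]])
      scores[[me$contig[1]]][idx[ok] + 1L] <-
        scores[[me$contig[1]]][idx[ok] + 1L] + shape[ok]
    }
    score_track(lapply(scores, as.numeric))
  })
}
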