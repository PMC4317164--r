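#' @title Synthetic splicing data with known ground truth
#' @description Generates multi-gene genomes carrying planted micro-exons
#' (constitutive, alternative, brain-specific; optionally withheld from the
#' annotation as "novel"), canonical GT/AG introns, planted splicing motifs
#' (ESE hexamers and a polypyrimidine tract for constitutive micro-exons,
#' TGCATG downstream of alternative ones), and per-sample reads whose
#' junction-informative fraction matches a specified true PSI. Also emits
#' multi-species alignments, conservation-style score tracks and coverage
#' tracks consistent with the planted structure.
#' @name simulate
NULL

#' Specify the micro-exon plan of one simulated gene
#'
#' @param lengths micro-exon lengths in nt (3-51); empty for a gene without
#'   micro-exons.
#' @param types one of "CS", "AS", "BS" per micro-exon.
#' @param novel logical per micro-exon; novel micro-exons are withheld from
#'   the annotation (to exercise discovery).
#' @param cluster integer cluster label per micro-exon; consecutive
#'   micro-exons sharing a label sit in tandem separated by a short intron
#'   (joint-enumeration territory), different labels are separated by a
#'   normal internal exon.
#' @return a gene-plan list consumed by \code{\link{sim_config}}.
#' @export
sim_gene <- function(lengths = integer(0), types = character(0),
                     novel = rep(FALSE, length(lengths)),
                     cluster = seq_along(lengths)) {
  stopifnot(length(types) == length(lengths), length(novel) == length(lengths),
            length(cluster) == length(lengths),
            all(types %in% c("CS", "AS", "BS")))
  list(lengths = as.integer(lengths), types = types, novel = novel,
       cluster = as.integer(cluster))
}

default_gene_plan <- function() {
  list(
    sim_gene(6, "CS"), sim_gene(12, "CS"), sim_gene(24, "CS"),
    sim_gene(45, "CS", cluster = 1L),
    sim_gene(9, "AS"), sim_gene(15, "AS"), sim_gene(24, "AS"),
    sim_gene(33, "AS"),
    sim_gene(12, "BS"), sim_gene(24, "BS"),
    sim_gene(c(12, 9), c("CS", "CS"), cluster = c(1L, 1L)),
    sim_gene()
  )
}

default_samples <- function() {
  data.frame(
    sample_id = c(paste0("brain", 1:6), paste0("muscle", 1:3),
                  paste0("nerve", 1:3), "pituitary1", paste0("liver", 1:3)),
    tissue = c(rep("brain", 6), rep("muscle", 3), rep("nerve", 3),
               "pituitary", rep("liver", 3)),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: 76-nt reads,
#' at most two substitutions per read expected, short GT/AG introns around
#' constitutive micro-exons with an 11-nt polypyrimidine tract at -20..-10
#' and ESE-tiled exon bodies, longer introns around alternative micro-exons
#' with TGCATG planted downstream at twice the background rate, and tissue
#' panels dominated by brain samples.
#'
#' @param genes list of \code{\link{sim_gene}} plans.
#' @param samples data.frame (sample_id, tissue).
#' @param read_length read length in nt (default 76).
#' @param depth mean per-transcript coverage per sample (default 30).
#' @param error_rate per-base substitution rate (default 0.002).
#' @param psi_cs,psi_as_range,psi_bs true PSI settings (percent): CS exons
#'   get \code{psi_cs} everywhere; AS exons draw one value per exon from
#'   \code{psi_as_range}; BS exons get \code{psi_bs["brain"]} in brain,
#'   \code{psi_bs["pituitary"]} in pituitary, \code{psi_bs["other"]}
#'   elsewhere.
#' @param cs_intron,as_intron,normal_intron intron length ranges in nt.
#' @param cluster_intron intron length between tandem clustered micro-exons.
#' @param flank_exon,internal_exon flanking/internal exon lengths.
#' @param ese_hexamers synthetic exonic-splicing-enhancer 6-mers tiled into
#'   CS micro-exon bodies.
#' @param u2af2_tract pyrimidine tract planted at -20..-10 upstream of CS
#'   micro-exons.
#' @param tgcatg_bg_rate background TGCATG planting rate per 100 nt of
#'   micro-exon intron flank.
#' @param tgcatg_as_mult multiplier for the downstream flank of AS/BS
#'   micro-exons (default 2).
#' @param motif_flank flank width (nt) within which motifs are planted.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(genes = default_gene_plan(),
                       samples = default_samples(),
                       read_length = 76, depth = 30, error_rate = 0.002,
                       psi_cs = 95, psi_as_range = c(20, 80),
                       psi_bs = c(brain = 70, pituitary = 40, other = 2),
                       cs_intron = c(280, 360), as_intron = c(600, 800),
                       normal_intron = c(900, 1200), cluster_intron = 60,
                       flank_exon = 150, internal_exon = 120,
                       ese_hexamers = c("GAAGAA", "TGGAAG", "AAGGAA",
                                        "GAAGGA", "CAAGAA", "GATGAA"),
                       u2af2_tract = "TTTTCTTTTCT",
                       tgcatg_bg_rate = 0.4, tgcatg_as_mult = 2,
                       motif_flank = 250) {
  structure(list(genes = genes, samples = samples, read_length = read_length,
                 depth = depth, error_rate = error_rate, psi_cs = psi_cs,
                 psi_as_range = psi_as_range, psi_bs = psi_bs,
                 cs_intron = cs_intron, as_intron = as_intron,
                 normal_intron = normal_intron, cluster_intron = cluster_intron,
                 flank_exon = flank_exon, internal_exon = internal_exon,
                 ese_hexamers = ese_hexamers, u2af2_tract = u2af2_tract,
                 tgcatg_bg_rate = tgcatg_bg_rate,
                 tgcatg_as_mult = tgcatg_as_mult, motif_flank = motif_flank),
            class = "sim_config")
}

rand_len <- function(range) {
  if (length(range) == 1) return(as.integer(range))
  as.integer(sample(range[1]:range[2], 1))
}

make_intron <- function(len) {
  stopifnot(len >= 4)
  paste0("GT", random_dna(len - 4L), "AG")
}

# Plant motif copies inside a window of an intron string (1-based indices
# [lo, hi] available for motif starts). Returns list(seq, starts).
plant_motif <- function(intron, motif, n, lo, hi) {
  w <- nchar(motif)
  starts <- integer(0)
  if (n > 0 && hi - w + 1 >= lo) {
    avail <- lo:(hi - w + 1)
    for (i in seq_len(n)) {
      ok <- avail[vapply(avail, function(p) all(abs(p - starts) >= w), logical(1))]
      if (length(ok) == 0) break
      p <- if (length(ok) == 1) ok else sample(ok, 1)
      substr(intron, p, p + w - 1L) <- motif
      starts <- c(starts, p)
    }
  }
  list(seq = intron, starts = sort(starts))
}

ese_body <- function(len, hexamers) {
  body <- paste(sample(hexamers, ceiling(len / 6), replace = TRUE), collapse = "")
  substr(body, 1, len)
}

#' Generate a synthetic genome with planted micro-exons
#'
#' Builds one contig per gene. Each gene is first exon / intron / (micro-exon
#' clusters separated by normal internal exons) / intron / last exon, with
#' every intron canonical (GT...AG). Half of the genes are placed on the
#' minus strand. Micro-exons flagged novel are withheld from the annotated
#' model (but present in the true model).
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed integer seed; the same seed reproduces the genome
#'   byte-identically.
#' @return object of class \code{sim_genome}: \code{$model_true} (all
#'   exons), \code{$model_annot} (novel micro-exons withheld), \code{$truth}
#'   (micro-exon table with types, base PSI and planted-motif table),
#'   \code{$config}.
#' @export
make_genome <- function(config, seed = 1) {
  with_seed(derive_seed(seed, 1), make_genome_impl(config))
}

make_genome_impl <- function(config) {
  contigs <- character(0)
  exon_rows <- list(); cds_rows <- list()
  micro_rows <- list(); motif_rows <- list()
  pad <- 200L
  for (gi in seq_along(config$genes)) {
    g <- config$genes[[gi]]
    contig <- sprintf("chr%d", gi)
    gene_id <- sprintf("gene%d", gi)
    tx <- sprintf("tx%d", gi)
    strand <- if (gi %% 2 == 0) "-" else "+"
    k <- length(g$lengths)

    for (attempt in 1:50) {
    gene_motifs <- list()
    # --- lay out in sense space: list of (kind, seq, micro-index)
    segs <- list()
    add <- function(kind, s, mi = NA_integer_) {
      segs[[length(segs) + 1L]] <<- list(kind = kind, seq = s, mi = mi)
    }
    add("exon", random_dna(config$flank_exon))
    if (k == 0) {
      add("intron", make_intron(rand_len(config$normal_intron)))
      add("exon", random_dna(config$internal_exon))
      add("intron", make_intron(rand_len(config$normal_intron)))
    } else {
      cl_ids <- unique(g$cluster)
      for (ci in seq_along(cl_ids)) {
        members <- which(g$cluster == cl_ids[ci])
        first_type <- g$types[members[1]]
        irange <- if (first_type == "CS") config$cs_intron else config$as_intron
        add("intron", make_intron(rand_len(irange)), members[1])
        for (j in seq_along(members)) {
          mi <- members[j]
          body <- if (g$types[mi] == "CS") {
            ese_body(g$lengths[mi], config$ese_hexamers)
          } else random_dna(g$lengths[mi])
          add("micro", body, mi)
          if (j < length(members)) {
            add("intron", make_intron(config$cluster_intron), members[j + 1L])
          }
        }
        last_type <- g$types[members[length(members)]]
        irange <- if (last_type == "CS") config$cs_intron else config$as_intron
        add("intron", make_intron(rand_len(irange)), -members[length(members)])
        if (ci < length(cl_ids)) add("exon", random_dna(config$internal_exon))
      }
    }
    add("exon", random_dna(config$flank_exon))

    # --- plant motifs in micro-adjacent introns
    # seg index of the intron before/after each micro
    for (si in seq_along(segs)) {
      sg <- segs[[si]]
      if (sg$kind != "intron" || is.na(sg$mi)) next
      mi <- abs(sg$mi)
      before <- sg$mi > 0   # intron 5' of micro mi (sense)
      type <- g$types[mi]
      L <- nchar(sg$seq)
      s <- sg$seq
      planted_tg <- integer(0)
      if (before && L >= 30) {
        if (type == "CS") {
          tract <- config$u2af2_tract
          # tract occupies exon-relative -20..-10 => intron indices L-19..L-9
          substr(s, L - 19L, L - 9L) <- tract
          gene_motifs[[length(gene_motifs) + 1L]] <- data.frame(
            gene_id = gene_id, mi = mi, motif = "U2AF2", flank = "up",
            rel_pos = -20L, stringsAsFactors = FALSE)
        }
        # background TGCATG in last motif_flank nt, clear of tract and AG
        n <- stats::rpois(1, config$tgcatg_bg_rate * config$motif_flank / 100)
        lo <- max(3L, L - config$motif_flank + 1L)
        res <- plant_motif(s, "TGCATG", n, lo, L - 26L)
        s <- res$seq
        if (length(res$starts)) {
          gene_motifs[[length(gene_motifs) + 1L]] <- data.frame(
            gene_id = gene_id, mi = mi, motif = "TGCATG", flank = "up",
            rel_pos = res$starts - L - 1L, stringsAsFactors = FALSE)
        }
      } else if (!before && L >= 30) {
        rate <- config$tgcatg_bg_rate *
          (if (type %in% c("AS", "BS")) config$tgcatg_as_mult else 1)
        n <- stats::rpois(1, rate * config$motif_flank / 100)
        hi <- min(L - 2L, config$motif_flank)
        res <- plant_motif(s, "TGCATG", n, 4L, hi)
        s <- res$seq
        if (length(res$starts)) {
          gene_motifs[[length(gene_motifs) + 1L]] <- data.frame(
            gene_id = gene_id, mi = mi, motif = "TGCATG", flank = "down",
            rel_pos = res$starts - 1L, stringsAsFactors = FALSE)
        }
      }
      segs[[si]]$seq <- s
    }

    # --- assemble contig (sense space), record exon coordinates
    sense <- paste0(random_dna(pad),
                    paste(vapply(segs, `[[`, character(1), "seq"), collapse = ""),
                    random_dna(pad))
    # uniqueness guard: each planted micro-exon body must occur exactly once
    # with AG]...[GT context in the gene, so discovery placement is exact
    bodies <- vapply(Filter(function(sg) sg$kind == "micro", segs),
                     `[[`, character(1), "seq")
    unique_ok <- all(vapply(bodies, function(b) {
      hits <- gregexpr(paste0("AG", b, "GT"), sense, fixed = TRUE)[[1]]
      sum(hits > 0) == 1L
    }, logical(1)))
    if (unique_ok) break
    if (attempt == 50) stop("could not build a uniquely-placeable gene: ",
                            gene_id)
    }
    motif_rows <- c(motif_rows, gene_motifs)
    L <- nchar(sense)
    off <- pad
    feat <- list()
    for (sg in segs) {
      len <- nchar(sg$seq)
      if (sg$kind != "intron") {
        feat[[length(feat) + 1L]] <- list(kind = sg$kind, mi = sg$mi,
                                          s = off, e = off + len)
      }
      off <- off + len
    }
    if (strand == "-") {
      contig_seq <- revcomp(sense)
      for (i in seq_along(feat)) {
        f <- feat[[i]]
        feat[[i]]$s <- L - f$e; feat[[i]]$e <- L - f$s
      }
    } else contig_seq <- sense
    contigs[contig] <- contig_seq

    for (f in feat) {
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        contig = contig, start = f$s, end = f$e, strand = strand,
        gene_id = gene_id, transcript_id = tx,
        kind = f$kind, mi = ifelse(is.na(f$mi), NA_integer_, f$mi),
        stringsAsFactors = FALSE)
      if (f$kind == "micro") {
        mi <- f$mi
        micro_rows[[length(micro_rows) + 1L]] <- data.frame(
          exon_id = exon_id_of(contig, f$s, f$e, strand),
          contig = contig, start = f$s, end = f$e, strand = strand,
          length = f$e - f$s, gene_id = gene_id, transcript_id = tx,
          type = g$types[mi], novel = g$novel[mi], cluster = g$cluster[mi],
          stringsAsFactors = FALSE)
      }
    }
  }

  exons <- do.call(rbind, exon_rows)
  truth_micro <- if (length(micro_rows)) do.call(rbind, micro_rows) else
    data.frame(exon_id = character(0), type = character(0), novel = logical(0))
  if (nrow(truth_micro) > 0) {
    truth_micro$base_psi <- ifelse(
      truth_micro$type == "CS", config$psi_cs,
      ifelse(truth_micro$type == "BS", unname(config$psi_bs["brain"]),
             round(runif(nrow(truth_micro), config$psi_as_range[1],
                         config$psi_as_range[2]), 1)))
  }
  motifs <- if (length(motif_rows)) do.call(rbind, motif_rows) else
    data.frame(gene_id = character(0), mi = integer(0), motif = character(0),
               flank = character(0), rel_pos = integer(0))
  if (nrow(motifs) > 0 && nrow(truth_micro) > 0) {
    key <- paste(truth_micro$gene_id, vapply(
      seq_len(nrow(truth_micro)), function(i) {
        sum(truth_micro$gene_id[seq_len(i)] == truth_micro$gene_id[i])
      }, numeric(1)))
    motifs$exon_id <- truth_micro$exon_id[match(paste(motifs$gene_id, motifs$mi), key)]
  }

  base_cols <- c("contig", "start", "end", "strand", "gene_id", "transcript_id")
  cds <- make_sim_cds(exons[base_cols], contigs)
  model_true <- genome_model(contigs, exons[base_cols], cds = cds,
                             source = "microx simulation")
  keep <- !(exons$kind == "micro" &
              exon_id_of(exons$contig, exons$start, exons$end, exons$strand) %in%
              truth_micro$exon_id[truth_micro$novel])
  model_annot <- genome_model(contigs, exons[keep, base_cols], cds = cds,
                              source = "microx simulation (annotated)")

  # canonical-context assertion: every planted micro-exon must be AG]..[GT
  if (nrow(truth_micro) > 0) {
    for (i in seq_len(nrow(truth_micro))) {
      dn <- edge_dinucs(model_true, truth_micro$contig[i], truth_micro$start[i],
                        truth_micro$end[i], truth_micro$strand[i])
      stopifnot(identical(dn$acceptor, "AG"), identical(dn$donor, "GT"))
    }
  }

  structure(list(model_true = model_true, model_annot = model_annot,
                 truth = list(micro = truth_micro, motifs = motifs),
                 config = config),
            class = "sim_genome")
}

# One CDS per transcript: transcript coords [30, spliced_len - 60) mapped
# back to genomic exon segments.
make_sim_cds <- function(exons, contigs) {
  rows <- list()
  for (tx in unique(exons$transcript_id)) {
    e <- exons[exons$transcript_id == tx, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (e$strand[1] == "-") e <- e[rev(seq_len(nrow(e))), , drop = FALSE]
    len <- e$end - e$start
    tot <- sum(len)
    cs <- 30L; ce <- tot - 60L
    if (ce <= cs) next
    cum <- cumsum(c(0L, len[-length(len)]))
    for (i in seq_len(nrow(e))) {
      a <- max(cs, cum[i]); b <- min(ce, cum[i] + len[i])
      if (b <= a) next
      if (e$strand[1] == "+") {
        gs <- e$start[i] + (a - cum[i]); ge <- e$start[i] + (b - cum[i])
      } else {
        ge <- e$end[i] - (a - cum[i]); gs <- e$end[i] - (b - cum[i])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        contig = e$contig[i], start = gs, end = ge, strand = e$strand[1],
        gene_id = e$gene_id[i], transcript_id = tx, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("sim_genome:", length(x$model_true$contigs), "gene contig(s),",
      nrow(x$truth$micro), "planted micro-exon(s) (",
      sum(x$truth$micro$novel), "novel )\n")
  invisible(x)
}

#' True per-sample PSI matrix of a simulated genome
#'
#' @param sim a \code{sim_genome}.
#' @param samples sample sheet (defaults to the config's).
#' @return matrix micro-exon x sample of true PSI in percent.
#' @export
psi_true <- function(sim, samples = sim$config$samples) {
  tm <- sim$truth$micro
  cfg <- sim$config
  m <- matrix(NA_real_, nrow(tm), nrow(samples),
              dimnames = list(tm$exon_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    t <- samples$tissue[j]
    m[, j] <- ifelse(tm$type != "BS", tm$base_psi,
                     if (t == "brain") unname(cfg$psi_bs["brain"])
                     else if (t == "pituitary") unname(cfg$psi_bs["pituitary"])
                     else unname(cfg$psi_bs["other"]))
  }
  m
}
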