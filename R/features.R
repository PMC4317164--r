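#' @title Splicing-feature characterization of exon classes
#' @description Flanking intron lengths, splice-site strength (pluggable
#' scorer), exonic-splicing-enhancer hexamer density over exon subregions,
#' nucleotide-content profiles, position-weight-matrix motif scanning with
#' the geometric-mean threshold, k-mer flank density, and the exact
#' hypergeometric set-overlap test.
#' @name features
NULL

#' Position probability matrix
#'
#' @param probs numeric matrix, one row per position, columns A/C/G/T (U is
#'   accepted for T). Each row must sum to 1 within 1e-9.
#' @param name motif name.
#' @return an object of class \code{pwm}.
#' @export
pwm <- function(probs, name = "pwm") {
  probs <- as.matrix(probs)
  colnames(probs) <- sub("^U$", "T", toupper(colnames(probs) %||%
                                              c("A", "C", "G", "T")))
  stopifnot(ncol(probs) == 4, all(c("A", "C", "G", "T") %in% colnames(probs)))
  probs <- probs[, c("A", "C", "G", "T"), drop = FALSE]
  if (any(abs(rowSums(probs) - 1) > 1e-9)) {
    stop("pwm rows must each sum to 1 (tolerance 1e-9)")
  }
  structure(list(name = name, width = nrow(probs), probs = probs),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm:", x$name, "- width", x$width, "\n")
  print(round(x$probs, 3))
  invisible(x)
}

#' Read a PWM from a tab-separated file (one row per position, columns
#' A C G T or A C G U)
#' @param path file path.
#' @param name motif name (defaults to the file name).
#' @export
read_pwm <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  header <- all(toupper(first) %in% c("A", "C", "G", "T", "U", "POS", ""))
  tb <- read.table(path, sep = "\t", header = header)
  tb <- tb[, vapply(tb, is.numeric, logical(1)), drop = FALSE]
  if (!header) colnames(tb) <- c("A", "C", "G", "T")
  pwm(as.matrix(tb), name = name)
}

#' Read a hexamer list (one 6-mer per line; U accepted for T)
#' @param path file path.
#' @param name set name.
#' @return character vector of 6-mers with a \code{name} attribute.
#' @export
read_hexamers <- function(path, name = basename(path)) {
  h <- toupper(trimws(readLines(path)))
  h <- chartr("U", "T", h[nzchar(h)])
  bad <- nchar(h) != 6 | grepl("[^ACGT]", h)
  if (any(bad)) stop("invalid hexamer(s): ", paste(head(h[bad], 3), collapse = ", "))
  structure(unique(h), name = name)
}

#' Exonic splicing enhancer hexamer density
#'
#' Density = (number of start positions whose 6-mer belongs to the set) /
#' (L - 5), counting overlapping matches, so the value is in [0, 1] and
#' comparable across lengths.
#'
#' @param seq exon (or subregion) sequence.
#' @param hexamer_set character vector of 6-mers.
#' @return density in [0, 1]; NA (with a message) when the sequence is
#'   shorter than 6 nt.
#' @export
ese_density <- function(seq, hexamer_set) {
  L <- nchar(seq)
  if (L < 6) {
    message("sequence shorter than 6 nt; ESE density undefined")
    return(NA_real_)
  }
  if (length(hexamer_set) == 0) return(0)
  starts <- seq_len(L - 5L)
  mean(substring(seq, starts, starts + 5L) %in% hexamer_set) # = hits/(L-5)
}

base_index <- function(seq) {
  match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
}

#' Scan a sequence with a PWM
#'
#' The score at position i is the sum over the motif width of
#' log(prob(observed base)), natural log, with zero-probability cells
#' floored at 1e-4. A position is a hit when its score reaches
#' \code{threshold}; the default, width x log(0.6), requires a geometric-mean
#' per-position probability of at least 0.6 and is invariant to the log base
#' as long as score and threshold share it.
#'
#' @param seq sequence to scan.
#' @param pwm a \code{\link{pwm}}.
#' @param threshold hit threshold (default \code{pwm$width * log(0.6)}).
#' @return data.frame (pos, score) of hit start positions (1-based); zero
#'   rows when the sequence is shorter than the motif.
#' @export
pwm_scan <- function(seq, pwm, threshold = pwm$width * log(0.6)) {
  w <- pwm$width
  L <- nchar(seq)
  empty <- data.frame(pos = integer(0), score = numeric(0))
  if (L < w) return(empty)
  logp <- log(pmax(pwm$probs, 1e-4))
  idx <- base_index(seq)
  n <- L - w + 1L
  score <- numeric(n)
  for (j in seq_len(w)) {
    b <- idx[j:(j + n - 1L)]
    contrib <- ifelse(is.na(b), log(1e-4), logp[j, ][b])
    score <- score + contrib
  }
  hit <- score >= threshold
  data.frame(pos = which(hit), score = score[hit])
}

#' Splice-site strength with a pluggable scorer
#'
#' Built-in scorers: a \code{\link{pwm}} object is scored as the summed
#' log2-odds against a uniform 0.25 background (a perfect match to a
#' degenerate-free 9-mer PWM scores 18); a named numeric vector (or
#' \code{\link{read_score_table}} result) is a lookup of precomputed scores
#' keyed by window sequence; a function is called as \code{scorer(window)}.
#'
#' @param window_seq donor (9-nt) or acceptor (23-nt) window sequence.
#' @param scorer a \code{pwm}, a named numeric vector, or a function.
#' @return numeric score (NA when a lookup table lacks the sequence).
#' @export
splice_site_score <- function(window_seq, scorer) {
  if (inherits(scorer, "pwm")) {
    if (nchar(window_seq) != scorer$width) {
      stop("window length ", nchar(window_seq), " does not match scorer width ",
           scorer$width)
    }
    idx <- base_index(window_seq)
    p <- pmax(scorer$probs[cbind(seq_len(scorer$width), idx)], 1e-4)
    return(sum(log2(p / 0.25)))
  }
  if (is.numeric(scorer) && !is.null(names(scorer))) {
    return(unname(scorer[window_seq])[1])
  }
  if (is.function(scorer)) return(scorer(window_seq))
  stop("unknown scorer type: ", class(scorer)[1])
}

#' Read a precomputed splice-site score table (TSV: sequence <tab> score)
#' @param path file path.
#' @return named numeric vector usable as a scorer.
#' @export
read_score_table <- function(path) {
  tb <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("seq", "score"),
                   colClasses = c("character", "numeric"))
  setNames(tb$score, toupper(tb$seq))
}

#' Exon subregion specifications
#'
#' Helpers describing which part of an exon a feature is computed over:
#' the whole exon, the central \code{n} nt (centered at floor(L/2),
#' left-shifted on ties), or \code{n5}+\code{n3} nt adjacent to the splice
#' sites.
#'
#' @param n,n5,n3 region sizes in nt.
#' @return a region specification list.
#' @export
region_whole <- function() list(kind = "whole")

#' @rdname region_whole
#' @export
region_central <- function(n = 24) list(kind = "central", n = n)

#' @rdname region_whole
#' @export
region_ss_adjacent <- function(n5 = 12, n3 = 12) {
  list(kind = "ss_adjacent", n5 = n5, n3 = n3)
}

#' @rdname region_whole
#' @param spec a region specification.
#' @param exon_seq exon sequence (sense orientation).
#' @export
resolve_region <- function(spec, exon_seq) {
  L <- nchar(exon_seq)
  switch(spec$kind,
         whole = exon_seq,
         central = {
           n <- min(spec$n, L)
           mid <- L %/% 2L                      # left-shifted on ties
           a <- max(1L, mid - (n %/% 2L) + 1L)
           substr(exon_seq, a, min(L, a + n - 1L))
         },
         ss_adjacent = {
           n5 <- min(spec$n5, L); n3 <- min(spec$n3, L)
           paste0(substr(exon_seq, 1L, n5), substr(exon_seq, L - n3 + 1L, L))
         },
         stop("unknown region kind: ", spec$kind))
}

#' Per-exon splicing features with per-class summaries
#'
#' For every exon: 5'/3' flanking intron length, donor/acceptor splice-site
#' score, and ESE density over each requested region. Per-class medians and
#' pairwise two-sided Mann-Whitney U tests are attached (classes with fewer
#' than 2 exons are omitted from the statistics).
#'
#' @param classes data.frame (exon_id, label).
#' @param model a \code{genome_model}.
#' @param hexamer_set ESE 6-mers.
#' @param scorer splice-site scorer (see \code{\link{splice_site_score}});
#'   scored windows are the 9-nt donor / 23-nt acceptor defaults.
#' @param regions named list of region specs (default whole exon).
#' @return list with \code{$per_exon}, \code{$medians} (class x feature) and
#'   \code{$tests} (class_a, class_b, feature, p_value).
#' @export
class_feature_table <- function(classes, model, hexamer_set,
                                scorer = NULL,
                                regions = list(whole = region_whole())) {
  rows <- lapply(seq_len(nrow(classes)), function(i) {
    id <- classes$exon_id[i]
    e <- parse_exon_id(id)
    fl <- flanking_introns(id, model)
    exon_seq <- get_seq(model, e$contig, e$start, e$end, e$strand)
    feat <- list(exon_id = id, label = classes$label[i],
                 length = nchar(exon_seq),
                 intron5_len = fl$upstream_length,
                 intron3_len = fl$downstream_length)
    if (!is.null(scorer)) {
      w <- splice_site_windows(id, model)
      feat$ss5_score <- splice_site_score(w$donor, scorer$donor %||% scorer)
      feat$ss3_score <- splice_site_score(w$acceptor, scorer$acceptor %||% scorer)
    }
    for (rn in names(regions)) {
      feat[[paste0("ese_", rn)]] <-
        suppressMessages(ese_density(resolve_region(regions[[rn]], exon_seq),
                                     hexamer_set))
    }
    as.data.frame(feat, stringsAsFactors = FALSE)
  })
  per_exon <- do.call(rbind, rows)
  feats <- setdiff(names(per_exon), c("exon_id", "label"))
  labs <- names(which(table(per_exon$label) >= 2))
  medians <- do.call(rbind, lapply(labs, function(l) {
    v <- per_exon[per_exon$label == l, feats, drop = FALSE]
    data.frame(label = l, feature = feats,
               median = vapply(feats, function(f) median(v[[f]], na.rm = TRUE),
                               numeric(1)),
               n = sum(per_exon$label == l), row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  tests <- list()
  if (length(labs) >= 2) {
    prs <- utils::combn(sort(labs), 2, simplify = FALSE)
    for (pr in prs) {
      for (f in feats) {
        x <- per_exon[per_exon$label == pr[1], f]
        y <- per_exon[per_exon$label == pr[2], f]
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        if (length(x) < 2 || length(y) < 2) next
        p <- suppressWarnings(wilcox.test(x, y, exact = NULL)$p.value)
        tests[[length(tests) + 1L]] <- data.frame(
          class_a = pr[1], class_b = pr[2], feature = f, p_value = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(per_exon = per_exon,
       medians = medians,
       tests = if (length(tests)) do.call(rbind, tests) else
         data.frame(class_a = character(0), class_b = character(0),
                    feature = character(0), p_value = numeric(0)))
}

# Clipped sense-orientation flank sequences of an exon: upstream positions
# -flank..-1 and downstream +1..+flank (NA-padded character matrices).
flank_chars <- function(exons, model, flank) {
  n <- nrow(exons)
  up <- matrix(NA_character_, n, flank)
  dn <- matrix(NA_character_, n, flank)
  for (i in seq_len(n)) {
    fl <- flanking_introns(exons$exon_id[i], model)
    ku <- min(flank, fl$upstream_length)
    if (ku > 0) {
      s <- substr(fl$upstream_seq, fl$upstream_length - ku + 1L,
                  fl$upstream_length)
      up[i, (flank - ku + 1L):flank] <- strsplit(s, "")[[1]]
    }
    kd <- min(flank, fl$downstream_length)
    if (kd > 0) {
      dn[i, 1:kd] <- strsplit(substr(fl$downstream_seq, 1L, kd), "")[[1]]
    }
  }
  list(up = up, dn = dn)
}

#' Per-position nucleotide-content profile around exons
#'
#' For each relative position -flank..-1 (upstream intron) and +1..+flank
#' (downstream intron), the fraction of exons whose sense-strand base equals
#' \code{base}. Flanks are clipped at neighboring exons; positions informed
#' by fewer than \code{min_exons} exons are masked.
#'
#' @param exons a \code{micro_exons}-like frame with exon_id.
#' @param model a \code{genome_model}.
#' @param flank window width in nt (default 100).
#' @param base the base whose frequency is profiled (default "T").
#' @param min_exons mask threshold (default 10).
#' @return data.frame (position, fraction, n).
#' @export
nt_content_profile <- function(exons, model, flank = 100, base = "T",
                               min_exons = 10) {
  fc <- flank_chars(exons, model, flank)
  frac_of <- function(m) {
    n <- colSums(!is.na(m))
    f <- colSums(m == base, na.rm = TRUE) / pmax(n, 1L)
    f[n < min_exons] <- NA_real_
    list(f = f, n = n)
  }
  u <- frac_of(fc$up); d <- frac_of(fc$dn)
  data.frame(position = c(-(flank:1), 1:flank),
             fraction = c(u$f, d$f), n = c(u$n, d$n))
}

#' Motif occurrence in an upstream intronic window
#'
#' Counts PWM hits whose motif lies entirely inside the window
#' \code{-window[1]..-window[2]} nt upstream of the exon start (sense
#' orientation; default -20..-10, the polypyrimidine-tract region), and
#' summarizes the mean number of hits per exon and the fraction of exons
#' with at least one hit, per class when a \code{label} column is present.
#'
#' @param exons frame with exon_id (and optionally label).
#' @param model a \code{genome_model}.
#' @param pwm a \code{\link{pwm}}.
#' @param window c(b, a): window spans positions -b..-a (default c(20, 10)).
#' @param threshold passed to \code{\link{pwm_scan}}.
#' @return list with \code{$per_exon} (exon_id, label, hits) and
#'   \code{$summary} (label, mean_hits, fraction_with_hit, n).
#' @export
motif_occurrence_window <- function(exons, model, pwm, window = c(20, 10),
                                    threshold = pwm$width * log(0.6)) {
  hits <- integer(nrow(exons))
  for (i in seq_len(nrow(exons))) {
    fl <- flanking_introns(exons$exon_id[i], model)
    b <- min(window[1], fl$upstream_length)
    if (b < pwm$width) next
    sub <- substr(fl$upstream_seq, fl$upstream_length - b + 1L,
                  fl$upstream_length - window[2] + 1L)
    hits[i] <- nrow(pwm_scan(sub, pwm, threshold))
  }
  label <- if ("label" %in% names(exons)) exons$label else "all"
  per_exon <- data.frame(exon_id = exons$exon_id, label = label, hits = hits,
                         stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(per_exon, per_exon$label), function(d) {
    data.frame(label = d$label[1], mean_hits = mean(d$hits),
               fraction_with_hit = mean(d$hits >= 1), n = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(per_exon = per_exon, summary = summ)
}

#' k-mer occurrence profile in intronic flanks, by class
#'
#' Counts k-mer start positions at each relative flank position (upstream
#' -flank..-1, downstream +1..+flank, positions of the k-mer start, sense
#' orientation, flanks clipped at neighbors) and aggregates per class. The
#' enrichment ratio between two classes is the ratio of their per-exon mean
#' counts within a flank.
#'
#' @param exons frame with exon_id and label columns.
#' @param model a \code{genome_model}.
#' @param kmer the k-mer (default "TGCATG", the RBFOX binding motif).
#' @param flank flank width in nt (default 250).
#' @return list with \code{$profile} (label, position, count),
#'   \code{$totals} (label, flank, n_exons, total, per_exon) and
#'   \code{$ratio(a, b, flank)} convenience accessor.
#' @export
kmer_flank_profile <- function(exons, model, kmer = "TGCATG", flank = 250) {
  k <- nchar(kmer)
  label <- if ("label" %in% names(exons)) exons$label else rep("all", nrow(exons))
  labs <- unique(label)
  counts <- list()
  n_exons <- table(factor(label, levels = labs))
  for (l in labs) {
    counts[[l]] <- list(up = numeric(flank), dn = numeric(flank))
  }
  for (i in seq_len(nrow(exons))) {
    fl <- flanking_introns(exons$exon_id[i], model)
    l <- label[i]
    ku <- min(flank, fl$upstream_length)
    if (ku >= k) {
      s <- substr(fl$upstream_seq, fl$upstream_length - ku + 1L,
                  fl$upstream_length)
      starts <- seq_len(ku - k + 1L)
      hit <- which(substring(s, starts, starts + k - 1L) == kmer)
      pos <- flank - ku + hit                  # column index for -flank..-1
      counts[[l]]$up[pos] <- counts[[l]]$up[pos] + 1
    }
    kd <- min(flank, fl$downstream_length)
    if (kd >= k) {
      s <- substr(fl$downstream_seq, 1L, kd)
      starts <- seq_len(kd - k + 1L)
      hit <- which(substring(s, starts, starts + k - 1L) == kmer)
      counts[[l]]$dn[hit] <- counts[[l]]$dn[hit] + 1
    }
  }
  profile <- do.call(rbind, lapply(labs, function(l) {
    data.frame(label = l, position = c(-(flank:1), 1:flank),
               count = c(counts[[l]]$up, counts[[l]]$dn),
               stringsAsFactors = FALSE)
  }))
  totals <- do.call(rbind, lapply(labs, function(l) {
    data.frame(label = l, flank = c("up", "down"),
               n_exons = as.integer(n_exons[[l]]),
               total = c(sum(counts[[l]]$up), sum(counts[[l]]$dn)),
               stringsAsFactors = FALSE)
  }))
  totals$per_exon <- totals$total / pmax(totals$n_exons, 1L)
  ratio <- function(a, b, flank = "down") {
    ta <- totals$per_exon[totals$label == a & totals$flank == flank]
    tb <- totals$per_exon[totals$label == b & totals$flank == flank]
    ta / tb
  }
  list(profile = profile, totals = totals, ratio = ratio)
}

#' Exact hypergeometric set-overlap test
#'
#' One-sided upper tail: the probability of observing at least
#' \code{n_overlap} common elements between random subsets of sizes
#' \code{n_a} and \code{n_b} drawn from a universe of size
#' \code{n_universe}.
#'
#' @param n_universe,n_a,n_b,n_overlap non-negative counts with
#'   \code{n_overlap <= min(n_a, n_b) <= n_universe}.
#' @return the exact p-value P(X >= n_overlap).
#' @export
overlap_test <- function(n_universe, n_a, n_b, n_overlap) {
  if (n_overlap < 0 || n_a < 0 || n_b < 0 ||
      n_a > n_universe || n_b > n_universe || n_overlap > min(n_a, n_b)) {
    stop("inconsistent counts: need 0 <= overlap <= min(A, B) <= universe")
  }
  phyper(n_overlap - 1, n_a, n_universe - n_a, n_b, lower.tail = FALSE)
}
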