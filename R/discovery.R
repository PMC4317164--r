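#' @title Micro-exon discovery from insertion-bearing alignments
#' @description From transcriptome-space alignments, reads carrying a
#' 3-51 nt insertion flanked by sufficient matches are collected; insertions
#' sitting exactly on annotated exon-exon boundaries are grouped, the
#' separating intron is scanned for the inserted sequence with canonical
#' AG]...[GT context, and candidates passing read-support and
#' expression-breadth filters become novel micro-exon calls.
#' @name discovery
NULL

CIGAR_RE <- "^(\\*|([0-9]+[MIDNSHP=X])+)$"

# asBam chokes on malformed CIGARs; drop such records with a warning.
clean_sam <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "@")
  cig <- vapply(strsplit(lines[body], "\t"), function(f)
    if (length(f) >= 6) f[6] else "", character(1))
  bad <- !grepl(CIGAR_RE, cig)
  if (any(bad)) {
    warning(sum(bad), " record(s) with malformed CIGAR skipped in ", path)
    keep <- rep(TRUE, length(lines))
    keep[which(body)[bad]] <- FALSE
    tmp <- tempfile(fileext = ".sam")
    writeLines(lines[keep], tmp)
    return(tmp)
  }
  path
}

#' Extract qualifying insertion events from transcriptome alignments
#'
#' Retains, from primary alignments against cDNA references, every insertion
#' of \code{min_len}..\code{max_len} nt flanked by at least \code{min_flank}
#' aligned-match nt on both sides, on reads with at most
#' \code{max_mismatch} substitutions (NM tag minus indel bases, when NM is
#' present).
#'
#' @param sam one or more SAM/BAM paths, or a data.frame from
#'   \code{read_sam_alignments}.
#' @param min_flank minimum matched nt on each side (default 6).
#' @param max_mismatch maximum substitutions per read (default 2).
#' @param min_len,max_len insertion size bounds (defaults 3 and 51).
#' @return data.frame of class \code{insertion_events}: read_id,
#'   transcript_id, insertion_offset (0-based transcript coordinate),
#'   inserted_seq, left_flank, right_flank, mismatches; a \code{summary}
#'   attribute counts dropped reads per filter.
#' @export
extract_insertions <- function(sam, min_flank = 6, max_mismatch = 2,
                               min_len = 3, max_len = 51) {
  if (is.character(sam) && length(sam) > 1) {
    evs <- lapply(sam, extract_insertions, min_flank = min_flank,
                  max_mismatch = max_mismatch, min_len = min_len,
                  max_len = max_len)
    out <- do.call(rbind, evs)
    sums <- lapply(evs, attr, "summary")
    attr(out, "summary") <- Reduce(function(a, b) Map(`+`, a, b), sums)
    class(out) <- c("insertion_events", "data.frame")
    return(out)
  }
  if (is.character(sam)) {
    if (grepl("\\.sam$", sam, ignore.case = TRUE)) sam <- clean_sam(sam)
    aln <- read_sam_alignments(sam)
  } else aln <- sam
  has_i <- grepl("I", aln$cigar, fixed = TRUE)
  cand <- aln[has_i, , drop = FALSE]
  rows <- list()
  n_fail <- c(len = 0L, flank = 0L, mismatch = 0L)
  if (nrow(cand) > 0) {
    ops_l <- GenomicAlignments::explodeCigarOps(cand$cigar)
    lens_l <- GenomicAlignments::explodeCigarOpLengths(cand$cigar)
    for (i in seq_len(nrow(cand))) {
      ops <- ops_l[[i]]; lens <- lens_l[[i]]
      if (cand$nm_sub[i] > max_mismatch) {
        n_fail["mismatch"] <- n_fail["mismatch"] + 1L
        next
      }
      qoff <- cumsum(ifelse(ops %in% c("M", "I", "S", "=", "X"), lens, 0L))
      roff <- cumsum(ifelse(ops %in% c("M", "D", "N", "=", "X"), lens, 0L))
      for (k in which(ops == "I")) {
        ilen <- lens[k]
        if (ilen < min_len || ilen > max_len) {
          n_fail["len"] <- n_fail["len"] + 1L
          next
        }
        left <- sum(lens[seq_len(k - 1L)][ops[seq_len(k - 1L)] %in% c("M", "=", "X")])
        right <- sum(lens[-seq_len(k)][ops[-seq_len(k)] %in% c("M", "=", "X")])
        if (left < min_flank || right < min_flank) {
          n_fail["flank"] <- n_fail["flank"] + 1L
          next
        }
        qstart <- if (k == 1) 0L else qoff[k - 1L]
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = cand$qname[i], transcript_id = cand$rname[i],
          insertion_offset = cand$start0[i] + (if (k == 1) 0L else roff[k - 1L]),
          inserted_seq = substr(cand$seq[i], qstart + 1L, qstart + ilen),
          left_flank = left, right_flank = right,
          mismatches = cand$nm_sub[i], stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(0), transcript_id = character(0),
               insertion_offset = integer(0), inserted_seq = character(0),
               left_flank = integer(0), right_flank = integer(0),
               mismatches = integer(0), stringsAsFactors = FALSE)
  attr(out, "summary") <- list(n_alignments = nrow(aln),
                               n_with_insertion = nrow(cand),
                               n_events = nrow(out),
                               n_fail_len = unname(n_fail["len"]),
                               n_fail_flank = unname(n_fail["flank"]),
                               n_fail_mismatch = unname(n_fail["mismatch"]))
  class(out) <- c("insertion_events", "data.frame")
  out
}

#' Group insertion events at annotated exon-exon boundaries
#'
#' Events whose insertion offset coincides exactly (tolerance 0) with an
#' exon-exon boundary of the reference transcript are grouped by (boundary,
#' inserted sequence); groups supported by fewer than \code{min_reads} reads
#' are discarded.
#'
#' @param events an \code{insertion_events} frame.
#' @param model the annotated \code{genome_model} the reads were aligned to.
#' @param min_reads minimum supporting reads (default 10).
#' @return data.frame of class \code{candidate_micro_exons}: up_exon,
#'   down_exon, inserted_seq, supporting_reads, transcripts.
#' @export
group_by_boundary <- function(events, model, min_reads = 10) {
  keys <- list()
  known_tx <- unique(model$exons$transcript_id)
  skipped <- 0L
  for (tx in unique(events$transcript_id)) {
    ev <- events[events$transcript_id == tx, , drop = FALSE]
    if (!(tx %in% known_tx)) {
      skipped <- skipped + nrow(ev)
      message("transcript not in model, skipping ", nrow(ev), " event(s): ", tx)
      next
    }
    e <- transcript_exons(model, tx)
    len <- e$end - e$start
    if (nrow(e) < 2) next
    bnd <- cumsum(len)[-nrow(e)]
    m <- match(ev$insertion_offset, bnd)
    hit <- !is.na(m)
    if (!any(hit)) next
    keys[[tx]] <- data.frame(
      up_exon = e$exon_id[m[hit]], down_exon = e$exon_id[m[hit] + 1L],
      inserted_seq = ev$inserted_seq[hit], transcript_id = tx,
      stringsAsFactors = FALSE)
  }
  if (length(keys) == 0) {
    out <- data.frame(up_exon = character(0), down_exon = character(0),
                      inserted_seq = character(0), supporting_reads = integer(0),
                      transcripts = character(0), stringsAsFactors = FALSE)
  } else {
    k <- do.call(rbind, keys)
    grp <- paste(k$up_exon, k$down_exon, k$inserted_seq, sep = "\r")
    tab <- table(grp)
    txs <- vapply(split(k$transcript_id, grp), function(t)
      paste(sort(unique(t)), collapse = ","), character(1))
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    out <- data.frame(up_exon = vapply(parts, `[`, character(1), 1),
                      down_exon = vapply(parts, `[`, character(1), 2),
                      inserted_seq = vapply(parts, `[`, character(1), 3),
                      supporting_reads = as.integer(tab),
                      transcripts = unname(txs[names(tab)]),
                      stringsAsFactors = FALSE)
    out <- out[out$supporting_reads >= min_reads, , drop = FALSE]
    out <- out[order(out$up_exon, out$down_exon, out$inserted_seq), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_skipped_events") <- skipped
  class(out) <- c("candidate_micro_exons", "data.frame")
  out
}

parse_exon_id <- function(id) {
  m <- regmatches(id, regexec("^(.+):(\\d+)-(\\d+):([+-])$", id))[[1]]
  list(contig = m[2], start = as.integer(m[3]), end = as.integer(m[4]),
       strand = m[5])
}

#' Place candidate inserted sequences inside the separating intron
#'
#' The intron between the boundary exons is scanned (sense orientation) for
#' exact occurrences of the inserted sequence immediately preceded by "AG"
#' and followed by "GT" within the intron. A unique hit is chosen directly;
#' among multiple hits one is drawn uniformly at random (flagged ambiguous)
#' with a per-candidate stream derived from \code{seed}, so reruns with the
#' same seed reproduce the same choice regardless of candidate order.
#'
#' @param candidates a \code{candidate_micro_exons} frame.
#' @param model the \code{genome_model}.
#' @param seed base seed for ambiguous choices (default 42).
#' @return the candidates with n_hits, ambiguous, placed, exon_id, contig,
#'   start, end, strand columns filled (NA where unplaceable).
#' @export
locate_in_intron <- function(candidates, model, seed = 42) {
  n <- nrow(candidates)
  candidates$n_hits <- rep(0L, n)
  candidates$ambiguous <- rep(FALSE, n)
  candidates$placed <- rep(FALSE, n)
  candidates$exon_id <- rep(NA_character_, n)
  candidates$contig <- rep(NA_character_, n)
  candidates$start <- rep(NA_integer_, n)
  candidates$end <- rep(NA_integer_, n)
  candidates$strand <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    up <- parse_exon_id(candidates$up_exon[i])
    dn <- parse_exon_id(candidates$down_exon[i])
    stopifnot(up$contig == dn$contig, up$strand == dn$strand)
    a <- min(up$end, dn$end); b <- max(up$start, dn$start)
    intron <- get_seq(model, up$contig, a, b, up$strand)
    ins <- candidates$inserted_seq[i]
    ilen <- nchar(ins); L <- nchar(intron)
    hits <- integer(0)
    p <- 1L
    repeat {
      j <- regexpr(ins, substr(intron, p, L), fixed = TRUE)
      if (j < 0) break
      pos <- p + as.integer(j) - 1L
      if (pos >= 3L && pos + ilen + 1L <= L &&
          substr(intron, pos - 2L, pos - 1L) == "AG" &&
          substr(intron, pos + ilen, pos + ilen + 1L) == "GT") {
        hits <- c(hits, pos)
      }
      p <- pos + 1L
      if (p > L - ilen + 1L) break
    }
    candidates$n_hits[i] <- length(hits)
    if (length(hits) == 0) next
    if (length(hits) == 1) {
      chosen <- hits
    } else {
      candidates$ambiguous[i] <- TRUE
      key <- sum(utf8ToInt(paste0(candidates$up_exon[i], ins))) %% 100000L
      chosen <- with_seed(derive_seed(seed, key), sample(hits, 1))
    }
    # sense position -> genomic interval
    if (up$strand == "+") {
      gs <- a + chosen - 1L
    } else {
      gs <- b - (chosen - 1L) - ilen
    }
    candidates$contig[i] <- up$contig
    candidates$start[i] <- gs
    candidates$end[i] <- gs + ilen
    candidates$strand[i] <- up$strand
    candidates$exon_id[i] <- exon_id_of(up$contig, gs, gs + ilen, up$strand)
    candidates$placed[i] <- TRUE
  }
  candidates
}

#' Ambiguity of candidate placements by insertion length
#'
#' @param candidates output of \code{\link{locate_in_intron}}.
#' @return data.frame (length, n_candidates, n_ambiguous,
#'   fraction_ambiguous) plus an "overall" row.
#' @export
ambiguity_report <- function(candidates) {
  len <- nchar(candidates$inserted_seq)
  by_len <- lapply(sort(unique(len)), function(l) {
    sel <- len == l
    data.frame(length = as.character(l), n_candidates = sum(sel),
               n_ambiguous = sum(candidates$ambiguous[sel]),
               fraction_ambiguous = mean(candidates$ambiguous[sel]),
               stringsAsFactors = FALSE)
  })
  overall <- data.frame(length = "overall", n_candidates = nrow(candidates),
                        n_ambiguous = sum(candidates$ambiguous),
                        fraction_ambiguous =
                          if (nrow(candidates)) mean(candidates$ambiguous) else 0,
                        stringsAsFactors = FALSE)
  rbind(do.call(rbind, by_len), overall)
}

#' Call novel micro-exons from placed candidates
#'
#' A placed candidate is called novel when its PSI is at least
#' \code{min_psi} percent in at least \code{min_sample_frac} of the samples
#' of at least one tissue, and its locus does not overlap any known internal
#' exon.
#'
#' @param candidates placed candidates from \code{\link{locate_in_intron}}.
#' @param pm a \code{psi_matrix} covering the candidate exon ids.
#' @param known_exons a \code{micro_exons}-like frame of annotated internal
#'   exons (contig, start, end, strand).
#' @param min_sample_frac expression-breadth fraction (default 0.15).
#' @param min_psi PSI threshold in percent (default 5).
#' @return a \code{micro_exons} data.frame with origin "novel".
#' @export
call_novel <- function(candidates, pm, known_exons, min_sample_frac = 0.15,
                       min_psi = 5) {
  cand <- candidates[candidates$placed, , drop = FALSE]
  n_absent <- 0L
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    id <- cand$exon_id[i]
    if (!(id %in% rownames(pm$values))) {
      n_absent <- n_absent + 1L
      message("candidate absent from PSI matrix, excluded: ", id)
      next
    }
    v <- pm$values[id, ]
    frac <- vapply(split(v, pm$tissues), function(x)
      sum(!is.na(x) & x >= min_psi) / length(x), numeric(1))
    if (!any(frac >= min_sample_frac)) next
    ov <- known_exons$contig == cand$contig[i] &
      known_exons$strand == cand$strand[i] &
      known_exons$start < cand$end[i] & known_exons$end > cand$start[i]
    if (any(ov)) next
    keep[i] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]
  k <- nrow(cand)
  out <- data.frame(exon_id = cand$exon_id, contig = cand$contig,
                    start = cand$start, end = cand$end, strand = cand$strand,
                    length = cand$end - cand$start,
                    origin = rep("novel", k),
                    acceptor_dinuc = rep("AG", k), donor_dinuc = rep("GT", k),
                    canonical = rep(TRUE, k), transcripts = cand$transcripts,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_absent_from_psi") <- n_absent
  class(out) <- c("micro_exons", "data.frame")
  out
}

#' Run the discovery pipeline through intron placement
#'
#' Convenience wrapper: extract insertion events from one or more
#' transcriptome SAMs, group them at exon-exon boundaries, and place them in
#' the separating introns. Breadth filtering (\code{\link{call_novel}})
#' requires quantification and is applied separately.
#'
#' @param sam_paths SAM/BAM files (typically one per sample, pooled).
#' @param model annotated \code{genome_model}.
#' @param min_flank,max_mismatch,min_len,max_len see
#'   \code{\link{extract_insertions}}.
#' @param min_reads see \code{\link{group_by_boundary}}.
#' @param seed see \code{\link{locate_in_intron}}.
#' @return placed \code{candidate_micro_exons}.
#' @export
discover_candidates <- function(sam_paths, model, min_flank = 6,
                                max_mismatch = 2, min_len = 3, max_len = 51,
                                min_reads = 10, seed = 42) {
  ev <- extract_insertions(sam_paths, min_flank = min_flank,
                           max_mismatch = max_mismatch,
                           min_len = min_len, max_len = max_len)
  cand <- group_by_boundary(ev, model, min_reads = min_reads)
  locate_in_intron(cand, model, seed = seed)
}
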