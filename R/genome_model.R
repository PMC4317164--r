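#' Coordinate-aware genome/annotation model
#'
#' The genome model holds contig sequences together with the
#' gene/transcript/exon hierarchy. All coordinates are stored 0-based
#' half-open; GTF/GFF3 input and output converts from/to 1-based inclusive.
#' Sequence accessors always return sense-strand (transcript-orientation)
#' sequence, so minus-strand features come back reverse-complemented.
#'
#' @param contigs named character vector of contig sequences (A/C/G/T/N).
#' @param exons data.frame with columns contig, start, end (0-based
#'   half-open), strand, gene_id, transcript_id; one row per exon-transcript
#'   membership.
#' @param cds optional data.frame of CDS segments with the same columns.
#' @param source free-text provenance string.
#' @return an object of class \code{genome_model}.
#' @export
genome_model <- function(contigs, exons, cds = NULL, source = "") {
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  req <- c("contig", "start", "end", "strand", "gene_id", "transcript_id")
  if (nrow(exons) > 0 && !all(req %in% names(exons))) {
    stop("exon table must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(exons) > 0) {
    exons$exon_id <- exon_id_of(exons$contig, exons$start, exons$end, exons$strand)
    bad <- exons$end <= exons$start
    if (any(bad)) stop("exon with end <= start: ", exons$exon_id[bad][1])
    clen <- nchar(contigs)[exons$contig]
    out <- is.na(clen) | exons$start < 0 | exons$end > clen
    if (any(out)) {
      stop("exon outside contig bounds: ", exons$exon_id[out][1],
           " (transcript ", exons$transcript_id[out][1], ")")
    }
    exons <- exons[order(exons$transcript_id, exons$contig, exons$start), ,
                   drop = FALSE]
    rownames(exons) <- NULL
    for (tx in unique(exons$transcript_id)) {
      e <- exons[exons$transcript_id == tx, , drop = FALSE]
      if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
        stop("transcript with overlapping exons: ", tx)
      }
    }
  } else {
    exons <- data.frame(contig = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        gene_id = character(0), transcript_id = character(0),
                        exon_id = character(0), stringsAsFactors = FALSE)
  }
  structure(list(contigs = contigs, exons = exons, cds = cds, source = source),
            class = "genome_model")
}

exon_id_of <- function(contig, start, end, strand) {
  sprintf("%s:%d-%d:%s", contig, start, end, strand)
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$contigs), "contig(s),",
      length(unique(x$exons$gene_id)), "gene(s),",
      length(unique(x$exons$transcript_id)), "transcript(s),",
      nrow(x$exons), "exon record(s)\n")
  invisible(x)
}

#' Load genome and annotation from FASTA + GTF/GFF3
#'
#' Reads an Ensembl-dialect GTF (gene_id/transcript_id attributes) or GFF3
#' (Parent attributes) together with the genome FASTA and builds a
#' \code{\link{genome_model}}. GTF 1-based inclusive coordinates are
#' converted to 0-based half-open.
#'
#' @param gtf path to a GTF or GFF3 file.
#' @param fasta path to the genome FASTA.
#' @param format "auto" (from extension), "gtf" or "gff3".
#' @return a \code{genome_model}.
#' @export
load_annotation <- function(gtf, fasta, format = c("auto", "gtf", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", gtf, ignore.case = TRUE)) "gff3" else "gtf"
  }
  fa <- Biostrings::readDNAStringSet(fasta)
  contigs <- setNames(as.character(fa), sub("\\s.*$", "", names(fa)))
  gr <- tryCatch(rtracklayer::import(gtf, format = format),
                 error = function(e) NULL)
  if (is.null(gr) || length(gr) == 0) {
    return(genome_model(contigs, data.frame(), source = gtf))
  }
  df <- as.data.frame(gr)
  get_tx <- function(d) {
    if (!is.null(d$transcript_id)) return(as.character(d$transcript_id))
    p <- vapply(d$Parent, function(x) if (length(x)) as.character(x)[1] else NA_character_,
                character(1))
    sub("^transcript:", "", p)
  }
  pick <- function(type) {
    d <- df[df$type == type, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    gid <- if (!is.null(d$gene_id)) as.character(d$gene_id) else get_tx(d)
    data.frame(contig = as.character(d$seqnames),
               start = d$start - 1L, end = d$end,
               strand = as.character(d$strand),
               gene_id = gid, transcript_id = get_tx(d),
               stringsAsFactors = FALSE)
  }
  ex <- pick("exon")
  if (is.null(ex)) return(genome_model(contigs, data.frame(), source = gtf))
  genome_model(contigs, ex, cds = pick("CDS"), source = gtf)
}

#' Write the exon (and CDS) structure of a model back to GTF
#'
#' @param model a \code{genome_model}.
#' @param path output file path.
#' @export
write_gtf <- function(model, path) {
  fmt <- function(d, type) {
    sprintf('%s\tmicrox\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            d$contig, type, d$start + 1L, d$end, d$strand, d$gene_id,
            d$transcript_id)
  }
  lines <- fmt(model$exons, "exon")
  if (!is.null(model$cds) && nrow(model$cds) > 0) {
    lines <- c(lines, fmt(model$cds, "CDS"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write contig sequences to FASTA
#' @param model a \code{genome_model}.
#' @param path output file path.
#' @export
write_genome_fasta <- function(model, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(model$contigs), path)
  invisible(path)
}

get_seq <- function(model, contig, start, end, strand = "+") {
  seq_slice(model$contigs[[contig]], start, end, strand)
}

# Exons of one transcript in transcript (5'->3') orientation.
transcript_exons <- function(model, tx) {
  e <- model$exons[model$exons$transcript_id == tx, , drop = FALSE]
  if (nrow(e) == 0) stop("unknown transcript: ", tx)
  e <- e[order(e$start), , drop = FALSE]
  if (e$strand[1] == "-") e <- e[rev(seq_len(nrow(e))), , drop = FALSE]
  e
}

# Spliced sense-strand sequence of a transcript (optionally with some exon
# ids dropped).
transcript_seq <- function(model, tx, drop_exons = character(0)) {
  e <- transcript_exons(model, tx)
  e <- e[!(e$exon_id %in% drop_exons), , drop = FALSE]
  paste(vapply(seq_len(nrow(e)), function(i) {
    get_seq(model, e$contig[i], e$start[i], e$end[i], e$strand[i])
  }, character(1)), collapse = "")
}

# Table of internal exons: one row per (exon, transcript) where the exon has
# both neighbors within that transcript. Adds genomic prev/next exon bounds.
internal_exon_table <- function(model) {
  ex <- model$exons
  if (nrow(ex) == 0) return(cbind(ex, prev_end = integer(0), next_start = integer(0)))
  res <- lapply(split(ex, ex$transcript_id), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    n <- nrow(e)
    if (n < 3) return(NULL)
    i <- 2:(n - 1)
    cbind(e[i, , drop = FALSE],
          prev_end = e$end[i - 1L], next_start = e$start[i + 1L])
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- cbind(ex[0, , drop = FALSE], prev_end = integer(0), next_start = integer(0))
  }
  rownames(out) <- NULL
  out
}

# Intron-edge dinucleotides in sense orientation for an exon interval.
edge_dinucs <- function(model, contig, start, end, strand) {
  clen <- nchar(model$contigs[[contig]])
  left_ok <- start >= 2; right_ok <- end + 2 <= clen
  left <- if (left_ok) get_seq(model, contig, start - 2L, start, "+") else NA_character_
  right <- if (right_ok) get_seq(model, contig, end, end + 2L, "+") else NA_character_
  if (strand == "+") {
    list(acceptor = left, donor = right)        # ..AG][exon][GT..
  } else {
    list(acceptor = if (right_ok) revcomp(right) else NA_character_,
         donor = if (left_ok) revcomp(left) else NA_character_)
  }
}

#' Identify internal micro-exons
#'
#' Scans the annotation for internal exons (exons with both an upstream and a
#' downstream neighbor in at least one transcript) whose length lies in
#' \code{[min_len, max_len]} and annotates each with its intron-edge
#' dinucleotides (sense orientation) and canonical GT/AG flag.
#'
#' @param model a \code{genome_model}.
#' @param min_len,max_len inclusive length bounds in nt (defaults 3 and 51).
#' @param origin origin label stamped on the result ("annotated" or "novel").
#' @return a data.frame of class \code{micro_exons} with one row per distinct
#'   genomic exon: exon_id, contig, start, end, strand, length, origin,
#'   acceptor_dinuc, donor_dinuc, canonical, transcripts (comma-separated).
#' @export
identify_micro_exons <- function(model, min_len = 3, max_len = 51,
                                 origin = "annotated") {
  it <- internal_exon_table(model)
  empty <- data.frame(exon_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), length = integer(0),
                      origin = character(0), acceptor_dinuc = character(0),
                      donor_dinuc = character(0), canonical = logical(0),
                      transcripts = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("micro_exons", "data.frame")
  if (nrow(it) == 0) return(empty)
  it$length <- it$end - it$start
  it <- it[it$length >= min_len & it$length <= max_len, , drop = FALSE]
  if (nrow(it) == 0) return(empty)
  tx_by_exon <- vapply(split(it$transcript_id, it$exon_id),
                       function(t) paste(sort(unique(t)), collapse = ","),
                       character(1))
  u <- it[!duplicated(it$exon_id), , drop = FALSE]
  dn <- lapply(seq_len(nrow(u)), function(i) {
    edge_dinucs(model, u$contig[i], u$start[i], u$end[i], u$strand[i])
  })
  out <- data.frame(exon_id = u$exon_id, contig = u$contig, start = u$start,
                    end = u$end, strand = u$strand, length = u$length,
                    origin = origin,
                    acceptor_dinuc = vapply(dn, `[[`, character(1), "acceptor"),
                    donor_dinuc = vapply(dn, `[[`, character(1), "donor"),
                    stringsAsFactors = FALSE)
  out$canonical <- !is.na(out$acceptor_dinuc) & !is.na(out$donor_dinuc) &
    out$acceptor_dinuc == "AG" & out$donor_dinuc == "GT"
  out$transcripts <- unname(tx_by_exon[out$exon_id])
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("micro_exons", "data.frame")
  out
}

# Resolve a micro-exon argument (exon_id string or 1-row data.frame) to the
# transcript that hosts it with the shortest total flanking introns
# (lexicographic transcript-id tie-break). Returns host transcript row info.
resolve_host <- function(micro_exon, model) {
  id <- if (is.character(micro_exon)) micro_exon else micro_exon$exon_id[1]
  it <- internal_exon_table(model)
  hits <- it[it$exon_id == id, , drop = FALSE]
  if (nrow(hits) == 0) stop("exon is not internal in any transcript: ", id)
  up_len <- hits$start - hits$prev_end
  dn_len <- hits$next_start - hits$end
  tot <- up_len + dn_len
  ord <- order(tot, hits$transcript_id)
  hits <- hits[ord[1], , drop = FALSE]
  hits
}

#' Flanking introns of a micro-exon
#'
#' Upstream/downstream are in transcript orientation (5' intron first). When
#' several transcripts give different neighbors, the transcript with the
#' smallest total flanking-intron length is used (ties broken by transcript
#' id).
#'
#' @param micro_exon an exon_id string or a 1-row \code{micro_exons} row.
#' @param model a \code{genome_model}.
#' @return a list with upstream_length, downstream_length, upstream_seq,
#'   downstream_seq (sense orientation) and the host transcript id.
#' @export
flanking_introns <- function(micro_exon, model) {
  h <- resolve_host(micro_exon, model)
  left_len <- h$start - h$prev_end          # genomic-left intron
  right_len <- h$next_start - h$end         # genomic-right intron
  left_seq <- get_seq(model, h$contig, h$prev_end, h$start, "+")
  right_seq <- get_seq(model, h$contig, h$end, h$next_start, "+")
  if (h$strand == "+") {
    res <- list(upstream_length = left_len, downstream_length = right_len,
                upstream_seq = left_seq, downstream_seq = right_seq)
  } else {
    res <- list(upstream_length = right_len, downstream_length = left_len,
                upstream_seq = revcomp(right_seq),
                downstream_seq = revcomp(left_seq))
  }
  res$transcript_id <- h$transcript_id
  res
}

#' Donor and acceptor splice-site windows
#'
#' Returns the 9-nt donor window (last \code{donor_window[1]} exonic nt plus
#' first \code{donor_window[2]} intronic nt of the downstream intron) and the
#' 23-nt acceptor window (last \code{acceptor_window[1]} intronic nt of the
#' upstream intron plus first \code{acceptor_window[2]} exonic nt), both in
#' sense orientation. Window sizes follow the common 9-mer/23-mer splice-site
#' scoring convention and are configurable.
#'
#' @param micro_exon exon_id string or \code{micro_exons} row.
#' @param model a \code{genome_model}.
#' @param donor_window c(exonic, intronic) sizes, default c(3, 6).
#' @param acceptor_window c(intronic, exonic) sizes, default c(20, 3).
#' @return list(donor =, acceptor =) character sequences.
#' @export
splice_site_windows <- function(micro_exon, model, donor_window = c(3, 6),
                                acceptor_window = c(20, 3)) {
  h <- resolve_host(micro_exon, model)
  fl <- flanking_introns(micro_exon, model)
  exlen <- h$end - h$start
  if (exlen < max(donor_window[1], acceptor_window[2])) {
    stop("exon too short for splice-site windows: ", h$exon_id)
  }
  if (fl$downstream_length < donor_window[2] ||
      fl$upstream_length < acceptor_window[1]) {
    stop("flanking intron shorter than splice-site window for exon ", h$exon_id)
  }
  exon_seq <- get_seq(model, h$contig, h$start, h$end, h$strand)
  donor <- paste0(substr(exon_seq, exlen - donor_window[1] + 1L, exlen),
                  substr(fl$downstream_seq, 1L, donor_window[2]))
  acceptor <- paste0(substr(fl$upstream_seq,
                            fl$upstream_length - acceptor_window[1] + 1L,
                            fl$upstream_length),
                     substr(exon_seq, 1L, acceptor_window[2]))
  list(donor = donor, acceptor = acceptor)
}

#' Write micro-exons as BED6 (0-based half-open)
#' @param micro_exons a \code{micro_exons} data.frame.
#' @param path output path.
#' @export
write_micro_exons_bed <- function(micro_exons, path) {
  bed <- data.frame(micro_exons$contig, micro_exons$start, micro_exons$end,
                    micro_exons$exon_id, 0L, micro_exons$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a micro-exon table as TSV
#' @param micro_exons a \code{micro_exons} data.frame.
#' @param path output path.
#' @export
write_micro_exons_tsv <- function(micro_exons, path) {
  write.table(micro_exons, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
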