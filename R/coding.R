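#' @title Protein-level consequence of micro-exon inclusion
#' @description Frame symmetry, coding potential (no in-frame stop inside
#' the inserted sequence), and the exact spliced-translation consequence
#' (in-frame insertion with its peptide, in-frame stop, or frameshift with
#' the distance to the first premature termination codon).
#' @name coding_impact
NULL

#' Is an exon length frame-symmetric?
#'
#' Symmetric exons (length a multiple of 3) preserve the reading frame when
#' included or skipped.
#'
#' @param length exon length in nt.
#' @return logical.
#' @export
is_symmetric <- function(length) {
  stopifnot(all(length >= 1))
  length %% 3 == 0
}

#' Coding potential of an inserted micro-exon sequence
#'
#' TRUE iff no stop codon (TAA/TAG/TGA) occurs in the reading frame set by
#' \code{phase} among codons lying fully inside the insertion. \code{phase}
#' is the number of leading inserted nt that complete the upstream codon,
#' so complete codons start at offset \code{phase} within the insertion.
#' Codons spanning the insertion junctions are handled by
#' \code{\link{inclusion_consequence}}.
#'
#' @param seq inserted sequence, sense orientation.
#' @param phase 0, 1 or 2.
#' @return logical.
#' @export
coding_potential <- function(seq, phase = 0) {
  stopifnot(phase %in% 0:2)
  !any(codons_of(seq, from = phase + 1L) %in% STOP_CODONS)
}

# CDS span of a transcript in transcript coordinates: c(start, end)
# 0-based half-open, or NULL if no CDS annotated.
cds_tx_span <- function(model, tx) {
  if (is.null(model$cds)) return(NULL)
  cd <- model$cds[model$cds$transcript_id == tx, , drop = FALSE]
  if (nrow(cd) == 0) return(NULL)
  e <- transcript_exons(model, tx)
  len <- e$end - e$start
  cum <- cumsum(c(0L, len[-length(len)]))
  spans <- vapply(seq_len(nrow(cd)), function(i) {
    j <- which(e$start <= cd$start[i] & e$end >= cd$end[i])[1]
    if (is.na(j)) return(c(NA_integer_, NA_integer_))
    if (e$strand[1] == "+") {
      a <- cum[j] + (cd$start[i] - e$start[j])
      b <- cum[j] + (cd$end[i] - e$start[j])
    } else {
      a <- cum[j] + (e$end[j] - cd$end[i])
      b <- cum[j] + (e$end[j] - cd$start[i])
    }
    c(a, b)
  }, integer(2))
  c(min(spans[1, ], na.rm = TRUE), max(spans[2, ], na.rm = TRUE))
}

#' Consequence of including a micro-exon in its host transcript
#'
#' Translates the spliced sequence with and without the micro-exon
#' (junction-spanning codons included). Symmetric, stop-free inclusions are
#' in-frame insertions and report the peptide of every codon overlapping
#' the insertion; symmetric inclusions that introduce a stop are in-frame
#' stops; non-symmetric inclusions are frameshifts. PTC offset is the
#' distance in nt from the insertion point to the first base of the first
#' novel stop codon downstream (NA when translation runs to the transcript
#' end without one).
#'
#' @param transcript transcript id (CDS must be annotated on it).
#' @param micro_exon exon_id string or \code{micro_exons} row; the exon
#'   must be spliced into this transcript's intron structure.
#' @param model a \code{genome_model} (the annotated model; the micro-exon
#'   may be absent from the transcript's exon chain).
#' @return list (kind, phase, ptc_offset, peptide); kind is one of
#'   "in-frame-insertion", "in-frame-stop", "frameshift",
#'   "non-coding-region".
#' @export
inclusion_consequence <- function(transcript, micro_exon, model) {
  id <- if (is.character(micro_exon)) micro_exon else micro_exon$exon_id[1]
  e <- parse_exon_id(id)
  me_df <- data.frame(exon_id = id, contig = e$contig, start = e$start,
                      end = e$end, strand = e$strand,
                      length = e$end - e$start, transcripts = transcript,
                      stringsAsFactors = FALSE)
  chain_in <- iso_chain(model, transcript, me_df, TRUE)
  chain_out <- chain_in[chain_in$exon_id != id, , drop = FALSE]
  row <- which(chain_in$exon_id == id)
  ins_off <- chain_in$iso_start[row]            # transcript coord (exclusion
  mlen <- e$end - e$start                       # isoform) of the insertion
  span <- cds_tx_span(model, transcript)   # exclusion-isoform coordinates,
  if (is.null(span)) stop("no CDS annotated on transcript: ", transcript)
  if (ins_off <= span[1] || ins_off >= span[2]) {   # like ins_off itself
    return(list(kind = "non-coding-region", phase = NA_integer_,
                ptc_offset = NA_integer_, peptide = NA_character_))
  }
  cds_a <- span[1]                         # unchanged in inclusion coords:
  seq_in <- chain_seq(model, chain_in)     # the CDS starts upstream of the
  offset_in_cds <- ins_off - cds_a         # insertion point
  phase_used <- offset_in_cds %% 3L             # nt of the current codon
  phase <- (3L - phase_used) %% 3L              # already consumed; inserted
  sym <- mlen %% 3L == 0L                       # nt completing it
  # translate the inclusion CDS from cds start
  cds_in <- substr(seq_in, cds_a + 1L, nchar(seq_in))
  cods <- codons_of(cds_in)
  cod_start0 <- (seq_along(cods) - 1L) * 3L     # codon starts, CDS coords
  ins_lo <- offset_in_cds; ins_hi <- offset_in_cds + mlen
  overl <- cod_start0 < ins_hi & cod_start0 + 3L > ins_lo
  stops_after <- which(cods %in% STOP_CODONS & cod_start0 + 3L > ins_lo)
  if (!sym) {
    ptc <- if (length(stops_after)) cod_start0[stops_after[1]] - ins_lo else NA_integer_
    return(list(kind = "frameshift", phase = phase,
                ptc_offset = ptc, peptide = NA_character_))
  }
  stop_in_ins <- length(stops_after) > 0 && overl[stops_after[1]]
  if (stop_in_ins) {
    return(list(kind = "in-frame-stop", phase = phase,
                ptc_offset = cod_start0[stops_after[1]] - ins_lo,
                peptide = NA_character_))
  }
  pep <- translate_dna(paste(cods[overl], collapse = ""))
  list(kind = "in-frame-insertion", phase = phase, ptc_offset = NA_integer_,
       peptide = pep)
}

#' Per-class coding-potential summary
#'
#' Fraction of micro-exons per class whose inserted sequence is stop-free
#' in its reading frame (the fast per-exon screen,
#' \code{\link{coding_potential}}).
#'
#' @param micro_exons \code{micro_exons} frame with a label column (or a
#'   separate \code{classes} frame).
#' @param model a \code{genome_model}.
#' @param classes optional data.frame (exon_id, label) if labels are not in
#'   \code{micro_exons}.
#' @return data.frame (label, n, n_coding, pct_coding) with percentages
#'   half-up rounded to one decimal.
#' @export
class_coding_summary <- function(micro_exons, model, classes = NULL) {
  if (!is.null(classes)) {
    micro_exons$label <- classes$label[match(micro_exons$exon_id,
                                             classes$exon_id)]
  }
  stopifnot("label" %in% names(micro_exons))
  coding <- logical(nrow(micro_exons))
  for (i in seq_len(nrow(micro_exons))) {
    e <- micro_exons[i, ]
    sq <- get_seq(model, e$contig, e$start, e$end, e$strand)
    tx <- strsplit(e$transcripts, ",")[[1]][1]
    ph <- 0L
    sp <- tryCatch(cds_tx_span(model, tx), error = function(err) NULL)
    if (!is.null(sp)) {
      me_df <- e
      me_df$transcripts <- tx
      ch <- iso_chain(model, tx, me_df, TRUE)
      off <- ch$iso_start[ch$exon_id == e$exon_id]
      if (off > sp[1] && off < sp[2]) {
        ph <- (3L - (off - sp[1]) %% 3L) %% 3L
      }
    }
    coding[i] <- coding_potential(sq, ph)
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(micro_exons)),
                                     micro_exons$label), function(idx) {
    data.frame(label = micro_exons$label[idx[1]], n = length(idx),
               n_coding = sum(coding[idx]),
               pct_coding = pct1(sum(coding[idx]), length(idx)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
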