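# Hand-built fixtures shared across tests. Sequences use a "C" background so
# AG/GT dinucleotides occur only where placed.

fill_seq <- function(n, base = "C") strrep(base, n)

set_sub <- function(s, start0, value) {
  substr(s, start0 + 1L, start0 + nchar(value)) <- value
  s
}

# Three-exon gene on chr (exons (100,150), (200,224), (300,400)):
# micro-exon of 24 nt with flanking introns of 50 and 76 nt, canonical
# splice sites on the requested strand. The exon ends "CAG", the downstream
# intron starts "GTAAGT", and the upstream intron ends in a T-tract + "AG"
# so splice-site windows are predictable.
toy_model <- function(strand = "+") {
  g <- fill_seq(500)
  if (strand == "+") {
    g <- set_sub(g, 150, "GT")
    g <- set_sub(g, 180, paste0(strrep("T", 18), "AG"))  # [180,200)
    g <- set_sub(g, 200, "GCT")                          # exon start
    g <- set_sub(g, 221, "CAG")                          # exon end
    g <- set_sub(g, 224, "GTAAGT")
    g <- set_sub(g, 298, "AG")
  } else {
    # mirror image: sense sequence comes from the reverse complement
    g <- set_sub(g, 221, "AGC")                          # sense exon starts "GCT"
    g <- set_sub(g, 200, "CTG")                          # sense exon ends "CAG"
    g <- set_sub(g, 224, paste0("CT", strrep("A", 18)))  # sense upstream intron
    g <- set_sub(g, 194, "ACTTAC")                       # ends "T..TAG"; sense
  }                                                      # downstream "GTAAGT.."
  exons <- data.frame(contig = "chr1",
                      start = c(100L, 200L, 300L),
                      end = c(150L, 224L, 400L),
                      strand = strand, gene_id = "g1", transcript_id = "t1",
                      stringsAsFactors = FALSE)
  genome_model(c(chr1 = g), exons)
}

# abutting-neighbor gene: introns of exactly 4 nt ("GTAG")
toy_abutting_model <- function() {
  g <- fill_seq(400)
  g <- set_sub(g, 150, "GTAG")       # intron [150,154)
  g <- set_sub(g, 160, "GTAG")       # intron [160,164)
  exons <- data.frame(contig = "chr1",
                      start = c(100L, 154L, 164L),
                      end = c(150L, 160L, 300L),
                      strand = "+", gene_id = "g1", transcript_id = "t1",
                      stringsAsFactors = FALSE)
  genome_model(c(chr1 = g), exons)
}

# Write a SAM file over a single reference
write_toy_sam <- function(records, refs, path = tempfile(fileext = ".sam")) {
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", names(refs), unname(refs)),
               records), path)
  path
}

sam_record <- function(qname, rname, pos1, cigar, seq, nm = 0, flag = 0) {
  sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
          qname, flag, rname, pos1, cigar, seq, nm)
}

# A small deterministic simulated study reused by several test files.
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config()
      cache <<- make_genome(cfg, seed = 101)
    }
    cache
  }
})

# Independent brute-force oracles -------------------------------------------

# hypergeometric upper tail via exact choose() sums (independent of phyper)
oracle_hyper_upper <- function(N, A, B, k) {
  x <- k:min(A, B)
  sum(choose(A, x) * choose(N - A, B - x)) / choose(N, B)
}

# window entropy recomputed column-by-column with explicit counting
oracle_entropy <- function(mat) {
  if (any(mat == "-")) return(NA_real_)
  tot <- 0
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    for (a in unique(col)) {
      f <- sum(col == a) / length(col)
      tot <- tot - f * log(f)
    }
  }
  tot
}
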