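#' @importFrom stats median quantile rbinom runif setNames wilcox.test phyper
#' @importFrom utils read.table write.table head tail
NULL

# Reverse-complement of plain character strings (vectorized).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Slice [start, end) (0-based half-open) out of a contig string; sense strand
# sequence is returned for strand == "-".
seq_slice <- function(contig_seq, start, end, strand = "+") {
  s <- substr(contig_seq, start + 1L, end)
  if (strand == "-") s <- revcomp(s)
  s
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Run code with a private RNG stream; the caller's RNG state is untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a stream seed from a base seed; kept below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483629)
}

# Half-up rounding to `digits` decimals (R's round() is half-even).
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

pct1 <- function(num, den) {
  ifelse(den == 0, 0, round_half_up(100 * num / den, 1))
}

translate_dna <- function(seq) {
  if (nchar(seq) < 3) return("")
  n <- (nchar(seq) %/% 3) * 3
  as.character(Biostrings::translate(Biostrings::DNAString(substr(seq, 1, n)),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

codons_of <- function(seq, from = 1L) {
  n <- nchar(seq)
  if (n - from + 1L < 3L) return(character(0))
  starts <- seq.int(from, n - 2L, by = 3L)
  substring(seq, starts, starts + 2L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
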