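---
title: "Micro-exon discovery, quantification and characterization: methods"
author: "microx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-exon discovery, quantification and characterization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microx)
```

# The problem

Micro-exons — internal exons of 3–51 nt — are hard for both the spliceosome
and for RNA-seq software. A 9-nt exon inside a 76-nt read leaves the aligner
a three-exon spanning problem with almost no anchor inside the exon itself,
so genome aligners under-report them; and the exon is so short that its
recognition depends unusually strongly on signals *outside* the exon:
splice-site strength, exonic splicing enhancers (ESEs), the polypyrimidine
tract bound by U2AF2, and intronic enhancers such as the (U)GCAUG motif
bound by RBFOX splicing factors.

`microx` implements the full computational path around these exons:

1. **Discovery** of unannotated micro-exons from insertion-bearing
   *transcriptome-space* alignments (`discovery` functions).
2. **Quantification** of inclusion by junction counting against an
   *augmented transcriptome* (`build_augmented`, `count_junctions`, `psi`).
3. **Classification** into constitutive (CS), alternative (AS) and
   brain-specific exons, plus differential inclusion between conditions.
4. **Feature characterization**: intron lengths, splice-site scores, ESE
   hexamer density, nucleotide-content and k-mer flank profiles, PWM motif
   scans, conservation and CLIP-coverage metagenes with bootstrap bands,
   alignment-entropy conserved 6-mer scans, and the protein-level
   consequence of inclusion.
5. A **synthetic-data generator** that produces genomes, annotations, reads,
   alignments, multiple sequence alignments and score tracks with known
   ground truth, so every stage is testable without external downloads.

# Discovery from insertion alignments

When reads are aligned to cDNA (transcript) references, a read that spans an
unannotated micro-exon aligns with an *insertion*: the flanking exon
sequence matches, and the micro-exon body appears as inserted bases exactly
at an exon–exon boundary. `extract_insertions` keeps insertions of 3–51 nt
flanked by at least 6 aligned-match nt on both sides, on reads with at most
2 substitutions (the NM tag minus indel bases). `group_by_boundary` groups
events that sit *exactly* on an annotated exon–exon boundary (tolerance
0 nt — the conservative and testable reading) and discards groups with fewer
than 10 supporting reads. `locate_in_intron` then searches the separating
intron for the inserted sequence with canonical context — immediately
preceded by `AG` and followed by `GT` in sense orientation, exact string
match only. When several loci qualify, one is drawn uniformly at random from
a stream derived from both the seed and the candidate's identity, so results
are reproducible regardless of candidate order (default seed 42).
`call_novel` finally requires expression breadth: PSI ≥ 5% in at least 15%
of the samples of at least one tissue, and no overlap with a known internal
exon. The 15% figure is the stated rule; the implied absolute count is
exposed through the `min_sample_frac` parameter rather than hard-coded.

# ATMap quantification

## The augmented transcriptome

For each transcript hosting micro-exons we build inclusion/exclusion
isoforms. Enumerating all $2^k$ combinations of $k$ micro-exons per gene is
unnecessary: a junction read can only span micro-exons that are close
together. Micro-exons are therefore clustered by single-linkage on genomic
gap ≤ 100 nt, and the isoform set is: the all-included backbone, the
all-excluded backbone, and — per cluster — every local $2^m$ combination
with out-of-cluster micro-exons included. This bounds the isoform count at
$\sum_c 2^{m_c} + 2$ while remaining exactly equivalent to full enumeration
for junction-read assignment (verified against brute force for clusters of
size ≤ 3 in the tests). Clusters larger than 12 raise an error rather than
silently exploding.

## PSI

With $R_L$ and $R_R$ the reads spanning the (upstream|micro) and
(micro|downstream) junctions and $R_{skip}$ the reads spanning the direct
(upstream|downstream) junction, support is

$$R_{tot} = \min(R_L, R_R), \qquad
  \mathrm{PSI} = 100 \cdot \frac{R_{tot}}{R_{tot} + R_{skip}}.$$

The min rule protects the estimate when an alternative 5′ or 3′ splice site
inflates one junction only (tested as an invariant: inflating $R_L$ alone
never moves PSI). A junction is "spanned" when the alignment covers at least
6 nt on both sides of it (`min_anchor`, mirroring the discovery flank rule;
configurable). PSI is reported missing when fewer than 6 informative reads
($R_{tot} + R_{skip} \le 5$) support it; the informative-read reading of the
masking rule is a deliberate choice, with the threshold exposed as
`min_informative`.

## Classification thresholds

Per exon, the median PSI over the non-missing samples of one tissue
(default `brain`) is compared against inclusive thresholds: median ≥ 90 →
CS; 10 ≤ median < 90 → AS; otherwise not expressed. Brain-specific exons
require a brain median PSI ≥ 25 *and* an 80th percentile ≤ 10 over all
pooled non-brain samples, excluding pituitary (biologically related to
brain; the exclusion is tested — a high pituitary PSI does not disqualify).
Differential inclusion between two conditions compares per-condition
medians and reports $|\Delta \mathrm{PSI}| > 15$, strictly.

# Feature analytics: conventions that matter

* **Splice-site windows** follow the common 9-mer donor (3 exonic + 6
  intronic nt) / 23-mer acceptor (20 intronic + 3 exonic nt) scoring
  convention, in sense orientation on both strands; sizes are parameters.
  `splice_site_score` is pluggable: a built-in log2-odds PWM scorer against
  a uniform 0.25 background, a lookup table of precomputed scores keyed by
  window sequence, or any user function.
* **ESE density** = (6-mer start positions belonging to the catalog) /
  $(L-5)$, counting overlapping matches — bounded in $[0,1]$ and comparable
  across exon lengths. The catalog (e.g. a 607-hexamer ESE set) is an input
  file, never vendored; tests use a small synthetic stand-in.
* **PWM scans** score 7-nt windows as $\sum_j \log p_j(x_j)$ with
  zero-probability cells floored at $10^{-4}$, and call a hit at score
  ≥ width × log(0.6). Natural log is used throughout; the threshold is the
  geometric-mean reading — per-position probability of at least 0.6 — which
  is invariant to the log base as long as score and threshold share it (a
  tested property).
* **"Central 24 nt"** of a long exon is centered at $\lfloor L/2 \rfloor$,
  left-shifted on ties. Mann–Whitney U tests are two-sided via
  `stats::wilcox.test` (exact for small samples without ties, normal
  approximation with tie correction otherwise).
* **The upstream motif window** −20..−10 nt counts PWM hits whose 7-mer
  lies entirely inside the window, with distinct start positions counted
  once (the choice between counting overlapping hits once or multiply was
  open; distinct starts is the bounded option).
* **`overlap_test`** reports the inclusive upper tail $P(X \ge k)$ of the
  hypergeometric; the probability of strictly exceeding an observed overlap
  is `overlap_test(N, A, B, k + 1)`. Both conventions appear in published
  work; the inclusive form is the one matching this package's exact
  enumeration oracle.

# Conservation analytics

* **Bootstrap profiles**: exons contribute fixed-width score vectors
  (default 300 nt centered on the exon midpoint; longer exons contribute
  their central window; minus-strand exons are flipped to transcript
  orientation). $B = 1000$ resamples of $|S|$ vectors with replacement give
  per-position means; the band is the 5th and 95th percentile of the
  bootstrap means (type-7 quantiles), i.e. a 90% interval — the output is
  labelled with that implied coverage.
* **Entropy scan**: for a gapless 6-column alignment window the score is
  $\sum_{i=1}^{6} -\sum_a f_{a,i} \ln f_{a,i}$; any gap excludes the window
  entirely. Conserved windows are those with entropy *below* the threshold
  (default 1.0, natural log — low entropy means conservation; both the
  threshold and log base are parameters and the base is recorded in
  output). The empirical-distribution threshold can be recomputed per
  region by filtering the scan output; the default applies one global
  threshold.
* **Percent identity** counts gap columns as mismatches, over 100-nt
  intronic flanks or the 12 exon-edge nt (6 from each end) to avoid
  exon-length bias.

# Coding impact

`coding_potential(seq, phase)` is the fast per-exon screen: no stop codon
among codons lying fully inside the inserted sequence. `phase` here is the
number of leading inserted nt that complete the upstream codon, so complete
codons start at offset `phase` in the insertion — e.g. `"ATAAGC"` at phase 1
reads `·A TAA GC·` and fails. `inclusion_consequence` is the exact
computation: it splices the micro-exon into its host transcript, translates
the CDS, and returns in-frame insertion (with the peptide over every codon
touching the insertion), in-frame stop, or frameshift with the distance to
the first premature termination codon; junction-spanning codons are handled
exactly there. Micro-exons outside the CDS are labelled `non-coding-region`
and excluded from class summaries. All reported percentages use half-up
rounding to one decimal (`percent_half_up`), since plain `round()` is
half-even.

# The synthetic-data generator

`sim_config`/`make_genome`/`simulate_reads` define the study conditions the
test suite and acceptance script run under:

* 76-nt single-end reads, per-base substitution rate 0.002 (so reads carry
  at most a couple of mismatches, matching the quantification filter),
  mean per-transcript coverage 30 by default.
* One gene per contig, half on the minus strand; every intron canonical
  GT…AG. CS-type micro-exons get short flanking introns (280–360 nt),
  ESE-tiled bodies, and an 11-nt pyrimidine tract at −20..−10; AS-type get
  longer introns (600–800 nt) and TGCATG planted downstream at twice the
  background rate (0.4/100 nt background, both flanks of every micro-exon).
  These levels make the planted contrasts detectable at desk scale without
  being caricatures; intron lengths for unconstrained internal exons are
  900–1200 nt.
* True PSI: CS 95 everywhere; AS one value per exon drawn from 20–80,
  constant across tissues; brain-specific exons 70 in brain, 40 in
  pituitary (exercising the pituitary exclusion), 2 elsewhere. The default
  sample panel is 6 brain, 3 muscle, 3 nerve, 1 pituitary, 3 liver samples.
* **Read generation is junction-local**: near each micro-exon cluster, the
  generating isoform is drawn per read with probability proportional to
  P(inclusion combination) × local-window width, which makes per-position
  depth equal across isoforms and the expected junction-spanning inclusion
  fraction *exactly* the true PSI — the estimator's target is well-defined
  by construction. (Drawing the combination by a plain Bernoulli and then
  placing the read uniformly within the chosen isoform over-weights the
  shorter exclusion window per position and biases PSI down; this is why
  the weighting exists.)
* Two alignment files per sample are emitted by construction (no aligner is
  run): perfect-coordinate SAM against the augmented transcriptome for
  quantification, and SAM against the annotated transcripts in which reads
  containing a withheld ("novel") micro-exon carry insertion CIGARs —
  deletions appear where an annotated micro-exon is skipped, and reads
  whose ends fall inside a novel exon are written unmapped since they
  cannot anchor.
* Each planted micro-exon body is checked at generation time to occur
  exactly once with `AG…GT` context within its gene (regenerating the gene
  otherwise), so discovery fixtures are uniquely placeable and recall can
  be asserted at exact loci.
* The MSA simulator uses a star phylogeny of 5 species with per-site
  substitution (2% inside planted conserved windows, 30% outside) and no
  indels; the score-track simulator is a smoothed indicator of planted
  conserved regions plus Gaussian noise clipped to [0,1]; the coverage
  simulator adds triangular peaks at planted downstream TGCATG sites over
  a Poisson background.

**What passing tests do and do not show.** The generator produces uniform
base composition, uniform coverage, independent substitution errors, exact
junction alignments and star-phylogeny alignments. Passing recovery tests
therefore demonstrates correctness of the *computations* (counting,
thresholds, enumeration, scans) under sampling noise — not robustness to
mappability artifacts, coverage biases, indel sequencing errors, alignment
uncertainty, or phylogenetic correlation structure in real data.

# Problem sizes and numerical checks

The shipped checks use desk-scale studies chosen to make the statistical
assertions sharp: estimator recovery runs 40 exons × 5 brain samples at
coverage 280 (≥ 200 informative reads per cell, so two binomial standard
errors are ≈ 5–7 PSI points at mid-range truth) over a true-PSI grid of
{10, 25, 50, 75, 90}; classification accuracy is asserted on planted types
whose truth sits away from the 90/10 boundaries (CS at 95, AS at 25–75),
since an exon whose true median lies exactly on a threshold is genuinely
ambiguous under sampling noise. Discovery runs 20 planted novel exons
spanning 6–51 nt across 8 samples. The entropy and hypergeometric
implementations are compared against independent brute-force oracles
(column-frequency counting; exact `choose()` sums over all configurations
with universe ≤ 30) at 1e-12 tolerance.

# Known limitations

* Quantification is junction-count based by design: no EM isoform
  abundance, no multi-mapping rescue; only primary alignments are counted.
* Discovery accepts primary alignments only and requires exact boundary
  coincidence; micro-exons expressed below the read-support or breadth
  thresholds are invisible by construction.
* The annotated-exon totals a run reports are whatever the supplied
  annotation yields; no attempt is made to reconcile count differences
  between alternative annotation releases.
* `read_score_track` materializes per-base vectors, which is appropriate
  for the simulated genomes and exon-flank analyses here, not for
  chromosome-scale tracks.
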