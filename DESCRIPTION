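Package: microx
Title: Micro-Exon Discovery, Quantification and Characterization from RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Discovers internal micro-exons (3-51 nt) from insertion-bearing
    transcriptome alignments, quantifies their inclusion (percent spliced-in,
    PSI) by junction counting against an augmented transcriptome, classifies
    them as constitutive, alternative or brain-specific, and characterizes
    their splicing-relevant genomic features: flanking intron lengths,
    splice-site strength, exonic splicing enhancer hexamer density,
    polypyrimidine content, RNA-binding protein motif scans, conserved k-mer
    entropy scans over multiple sequence alignments, conservation and CLIP
    coverage metagene profiles with bootstrap confidence intervals, and the
    protein-level consequence of micro-exon inclusion. Includes a synthetic
    data generator producing genomes, annotations, reads, alignments, MSAs
    and score tracks with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
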