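Package: parclipr
Title: PAR-CLIP Peak Calling with a Poisson Background Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies RNA-binding protein interaction sites from PAR-CLIP
    sequencing alignments. Builds strand-specific per-base mismatch tracks
    from a BAM file and reference genome, estimates a transcriptome-wide
    background mismatch rate from the eleven non-T-to-C substitution types,
    derives candidate read groups from coverage, tests each group for
    T-to-C enrichment with an exact one-sided Poisson test under
    Benjamini-Hochberg false discovery rate control, and annotates called
    clusters to genomic features from an ENSEMBL-style GTF. Also provides
    read preprocessing (duplicate collapsing, UMI trimming, length
    filtering), quality-control utilities (substitution spectra, normalized
    mismatch signal tracks, multi-set overlap matrices, per-gene T-to-C
    correlation), and a seeded synthetic PAR-CLIP read simulator with known
    truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
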