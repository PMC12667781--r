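# parclipr

PAR-CLIP peak calling with a Poisson background model.

PAR-CLIP experiments identify the binding sites of RNA-binding proteins
(RBPs): 4-thiouridine incorporated into nascent RNA crosslinks to bound
protein under UV light and leaves a diagnostic **T-to-C transition** in the
sequenced cDNA at the crosslink site. The analysis challenge is separating
this signal from sequencing, reverse-transcription and SNP noise. `parclipr`
is for RNA biologists and bioinformaticians who have aligned PAR-CLIP reads
(a coordinate-sorted BAM) and want statistically calibrated interaction
sites with minimal machinery.

## The method

From strand-specific per-base mismatch tracks the package estimates a
transcriptome-wide null T-to-C rate from the 11 substitution types that
crosslinking cannot produce:

```
R = M / (11 N)
```

where `N` is the total number of quality-passing sequenced bases and `M`
the total non-T-to-C mismatch count. Candidate *read groups* — contiguous
runs of positions with depth ≥ 3, merged and then split to at most 50 nt —
are tested with the exact one-sided Poisson test: for group *i* with `n_i`
sequenced bases and `O_i` observed T-to-C events,
`p_i = P(X ≥ O_i), X ~ Poisson(R·n_i)`. Benjamini–Hochberg correction is
applied over all tested groups in one family, and groups with **q ≤ 0.05**
are reported as clusters, then annotated against an ENSEMBL-style GTF with
the priority 3'UTR > CDS > 5'UTR > intron (non-coding genes contribute
their biotype; multi-gene overlaps are tagged `multigenic`).

The package also ships read preprocessing (duplicate collapsing, UMI
trimming, 13-nt length filter), QC utilities (12-type substitution
spectrum, CPM-normalized mismatch signal tracks, 2–3-way BED overlap
matrices, per-gene T-to-C correlation across samples) and a seeded
synthetic PAR-CLIP simulator with known truth, so the entire pipeline is
verifiable offline.

## Worked example

Simulate a 50-kb genome with 20 planted binding sites (30% T-to-C
conversion at the sites, 0.1% uniform sequencing error), then call peaks:

```r
library(parclipr)

cfg   <- sim_config(seed = 42, genome_length = 50000, n_sites = 20)
sim   <- simulate_parclip(cfg, file.path(tempdir(), "demo"))
calls <- call_peaks(sim$paths$bam, sim$paths$fasta)
glance(calls)
#> # A tibble: 1 × 7
#>   n_groups n_clusters n_rejected alpha      rate n_total m_background
#>      <int>      <int>      <int> <dbl>     <dbl>   <dbl>        <dbl>
#> 1     2610         22       2588  0.05 0.0000778  408990          350
```

2,610 read groups were tested; 22 passed FDR control. The estimated null
rate 7.78e-05 is the per-base probability of a background T-to-C — close to
its theoretical value under the simulator's noise model (error rate / 12 =
8.3e-05). The clusters themselves:

```r
head(clusters(calls)[, c("chrom", "start", "end", "name", "strand",
                         "n_bases", "o_t2c", "expected", "q_value")], 4)
#> # A tibble: 4 × 9
#>   chrom  start   end name  strand n_bases o_t2c expected  q_value
#>   <chr>  <int> <int> <chr> <chr>    <int> <int>    <dbl>    <dbl>
#> 1 chrSim  3226  3262 CL1   +          511    37   0.0398 3.92e-93
#> 2 chrSim  5335  5377 CL2   +          586    15   0.0456 7.69e-31
#> 3 chrSim  6682  6721 CL3   -          566    14   0.0440 1.48e-28
#> 4 chrSim  8548  8587 CL4   -          549    23   0.0427 2.05e-52
```

Each cluster reports its exposure (`n_bases`), observed T-to-C count
(`o_t2c`), Poisson expectation under the background model (`expected`) and
BH-adjusted q-value: CL1 carries 37 conversions where 0.04 were expected.
All 20 planted sites overlap a called cluster. `annotate_bed()` /
`annotate_intervals()` add feature, gene name and gene id columns, and
`autoplot(calls)` draws observed-vs-expected T-to-C per group.

A thin command-line front end covering the same steps is installed at
`inst/exec/parclipr` (subcommands `preprocess`, `tracks`, `call`,
`annotate`, `spectrum`, `track`, `compare`, `simulate`).

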