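---
title: "Calling PAR-CLIP interaction sites with a Poisson background model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling PAR-CLIP interaction sites with a Poisson background model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parclipr)
```

## The problem

PAR-CLIP identifies the binding sites of an RNA-binding protein (RBP)
transcriptome-wide. Cells are fed 4-thiouridine (4SU), which is incorporated
into nascent RNA; UV irradiation crosslinks 4SU to bound protein, and the
crosslinked base preferentially pairs with G during reverse transcription.
The sequenced cDNA therefore carries a diagnostic T-to-C transition at the
crosslink position. The analysis problem is to separate genuine
crosslink-induced T-to-C signal from the background of SNPs, reverse
transcription and PCR errors, and base-calling noise that any deep
sequencing library carries.

`parclipr` implements a deliberately simple statistical treatment of this
problem: the eleven substitution types that crosslinking cannot produce are
used to estimate how often a mismatch arises for non-crosslink reasons, and
each candidate region is then asked whether its T-to-C count exceeds what
that background rate predicts.

## The model

Let $N$ be the total number of quality-passing sequenced bases across both
strands (the sum of per-position read depths) and $M$ the total count of
non-T-to-C mismatches. The null per-base T-to-C rate is

$$R = \frac{M}{11 \, N}.$$

Dividing the pooled background mismatch rate $M/N$ by 11 — the number of
background substitution types — converts it into the rate of a *single*
substitution type. Under the null hypothesis of no crosslinking, T-to-C is
just one more error type, so $R$ is its expected per-base rate. This is a
design decision worth stating plainly: one could instead use $M/N$
unadjusted (treating any mismatch as equally likely at a given position) or
$11M/N$; we consider the per-type reading the only dimensionally coherent
choice for the test below, and `estimate_background(divisor = )` exposes the
denominator for users who disagree. When $M = 0$ (which happens on clean
simulated data, never on real libraries) the rate is floored at $1/(11N)$ so
that no p-value is exactly zero.

Candidate regions ("read groups") are maximal runs of positions with depth
at least `min_depth` (default 3), optionally merged across gaps of at most
`gap` bases (default 0, i.e. only book-ended runs merge), and then split so
that no region exceeds `max_width` bases (default 50; most RBP footprints
are under 20 nt, and unsplit low-complexity pileups would otherwise be
tested as single implausibly long sites). A region of width $L$ is tiled by
$\lceil L/\mathrm{max\_width} \rceil$ contiguous pieces whose widths differ
by at most one base. Equal tiling, rather than greedy 50-base chunks with a
remainder, avoids systematically under-powered terminal fragments; this is
our choice where only the width bound itself is prescribed.

For read group $i$ with $n_i$ total sequenced bases and $O_i$ observed
T-to-C events, the expected count is $\lambda_i = R \, n_i$ and the p-value
is the exact upper tail

$$p_i = P(X \ge O_i), \qquad X \sim \mathrm{Poisson}(R\,n_i),$$

identical to the one-sided exact rate test
`poisson.test(O_i, n_i, R, alternative = "greater")`. All tested groups —
both strands, genome-wide — form a single Benjamini–Hochberg family, and
groups with $q \le 0.05$ (inclusive) are reported as clusters. Groups with
$O_i = 0$ are retained through testing with $p = 1$: dropping them would
shrink the BH family and make the correction anti-conservative.

## Counting mismatches

Tracks are built per strand from a coordinate-sorted BAM and the reference
FASTA. Reads must be primary (FLAG 0x100 clear) with MAPQ at or above 55 —
with STAR-style alignments, where unique mappers receive MAPQ 255, this is
exactly a unique-mapper filter. Duplicate-marked (0x400) and supplementary
(0x800) records are also excluded (duplicates are normally removed upstream
by collapsing; supplementary records would double-count). Bases below
quality 20, read-base `N`s and reference `N` positions are excluded from
*both* the depth denominator and the mismatch numerator — the stated
thresholds could arguably apply to the numerator only, but filtering both
keeps the rate estimate internally consistent. Insertions and deletions are
ignored; crosslinking produces substitutions only.

Mismatches are classified strand-locally: for minus-strand reads both the
reference and read base are complemented before comparison, so a
strand-local T-to-C equals a reference-space A-to-G. This follows the
chemistry — crosslinking acts on the transcript's uridine, whichever genome
strand encodes it. All coordinates are 0-based half-open internally and in
every BED/bedGraph written. The per-position depth cap is $10^7$,
effectively unbounded, so deep libraries are counted in full.

## Preprocessing

`preprocess_reads()` implements the read-level steps the caller defines for
itself (adapter trimming belongs to a dedicated trimmer and is out of
scope): exact-duplicate collapsing to distinct sequences with copy counts,
a minimum-length filter at 13 nt, fixed-length UMI removal from either end,
and the length filter again after trimming. Sequences are uppercased before
collapsing, and `N`-containing reads are retained and collapsed by exact
match. Collapsing before UMI removal can under-collapse UMI-bearing
duplicates (two copies of one molecule with different UMIs stay distinct);
we keep this ordering deliberately — it matches the upstream pipeline the
package mirrors, and changing it would change cluster counts on real data.

## Annotation

Clusters are annotated against an ENSEMBL-style GTF. Overlap is
strand-matched (configurable) with a 1-bp minimum — clusters are at most 50
nt, so fractional-overlap rules would add little. A cluster overlapping
more than one gene is tagged `multigenic`; a single non-protein-coding gene
contributes its biotype (miRNA, rRNA, ...); a single coding gene is resolved
through the hierarchy 3'UTR > CDS > 5'UTR > intron, applied across the union
of the gene's transcript features. Introns are derived as the gene span
minus the union of its exons. tRNAs are absent from canonical GTFs and are
therefore never assigned.

## The synthetic generator

`simulate_parclip()` produces truth-known data so that the whole pipeline is
testable without downloads: a random reference (uniform base composition by
default), non-overlapping planted sites of 25 nt each containing at least
three strand-local Ts, ungapped 30-nt single-end reads (typical PAR-CLIP
insert sizes after trimming), site reads covering their site at depth 15,
background coverage at mean depth 8, T-to-C conversion at rate 0.3 inside
sites, and a uniform per-base substitution error (rate 0.001 by default;
each error is uniform over the three alternative bases). Uniform errors are
chosen deliberately: under uniform composition exactly $11/12$ of errors
are non-T-to-C, so the background estimator has the closed-form expectation
$R \to e/12$ for error rate $e$ — a calibration the tests check directly.
Site/conversion/depth defaults follow the generator's role as the package's
study condition and are not tuned per analysis.

The generator is seeded and byte-deterministic (identical configurations
give identical FASTA/SAM/BED/GTF files). It does *not* emulate several
properties of real libraries: fragment-length and positional bias,
quality-score variation, PCR duplicates, spliced alignments, SNPs, or
non-uniform error spectra. Passing tests on simulated data therefore
demonstrate the correctness of the counting and testing machinery and the
calibration of the statistics under the stated noise model — not robustness
to every artifact of real data.

## Verification at desk scale

The test suite checks, among other things: exactness of the Poisson upper
tail against direct pmf summation (relative error below $10^{-12}$ over
$\lambda \in [0.01, 50]$, $O \le 200$); BH against a brute-force
sorted-cumulative-minimum implementation on 1,000 random vectors; the
pileup against an independent per-read reference walk on 200 randomized
small alignments; exact tiling and width bounds of the interval algebra on
randomized coverage; false-discovery calibration on 20 fully-null
simulations of a 200-kb genome at error rate 0.002 (mean false-discovery
proportion at or below 0.05); and recovery of at least 90% of planted
sites across 10 seeded simulations at the default conditions. These
problem sizes keep a full verification run in a few minutes on one core
while leaving each check statistically meaningful.

## Known limitations

* The background model pools both strands and the entire transcriptome into
  one rate; locally elevated error rates (e.g. SNP clusters) are not
  modeled, and no external VCF masking is performed.
* With `gap > 0`, merged groups may include interior sub-threshold columns
  in $n_i$; the default `gap = 0` avoids this.
* The bedGraph triple round-trips depth and mismatch counts exactly, but
  the reference base is not representable in the format and is `NA` after
  reading back.
* The annotation resolves features across the union of a gene's
  transcripts; isoform-resolved assignment is out of scope.
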