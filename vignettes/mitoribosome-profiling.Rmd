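---
title: "Codon-level analysis of mitoribosome profiling data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-level analysis of mitoribosome profiling data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoriboseq)
```

## The biological problem

Human mitochondria translate thirteen mtDNA-encoded OXPHOS subunits with a
dedicated ribosome (the 55S mitoribosome) and a minimal decoding apparatus:
only 22 mt-tRNAs, so many sense codons are read through non-canonical wobble
pairing, UGA is recoded to tryptophan, AGA/AGG act as stops, and AUA/AUU serve
as initiator codons alongside AUG. Most mt-mRNAs are leaderless — translation
starts at, or within a few nucleotides of, the transcript 5' end — while two
bicistronic transcription units carry a downstream reading frame whose start
codon is internal, overlapping the upstream frame. Several ORFs end in an
incomplete stop codon completed to UAA by polyadenylation.

Mitoribosome profiling sequences the mRNA fragments (protected footprints,
24–37 nt here) shielded by translating mitoribosomes. `mitoriboseq` takes
*aligned* footprints plus an annotated mitochondrial reference and asks, at
codon resolution:

1. Is any codon identity over- or under-represented in footprints relative to
   its genomic frequency (a proxy for differential ribosome dwell, e.g. from
   wobble pairing)?
2. Do two cell lines (e.g. control vs a mutant with an altered mitoribosome)
   differ in per-codon occupancy?
3. How do footprints stack up around initiation sites — at leaderless 5'
   termini, short 1–3 nt leaders, and internal (bicistronic) starts?
4. Do replicate libraries cluster as expected, and apart from the genomic
   codon-usage profile?
5. Are the amino-terminal decapeptides hydrophobic (GRAVY), a candidate
   explanation for early-elongation pausing?

Everything upstream of aligned footprints (trimming, rRNA/tRNA filtering,
alignment) is out of scope.

## The statistical model

**Profiles.** For each replicate library the *fractional footprint profile*
is a 64-vector: footprint counts assigned to each codon identity, divided by
the replicate's total read count. The *fractional abundance profile* is the
genomic codon-usage vector over the coding regions, normalized to sum to 1;
it is the biological null for dwell analysis. Overlapping ORFs are counted
once per frame, because each frame is independently translated.

**Tests.** Per codon, a two-tailed one-sample t-test compares the `n`
replicate fractions against the abundance fraction
(`t = (x̄ − μ₀)/(s/√n)`, `n − 1` df); condition comparisons use a two-tailed
two-sample t-test (Welch by default, matching `t.test`; pooled variance is
available). Each 64-test family is corrected by Benjamini–Hochberg step-up
FDR, and codons with `q < 0.05` are called significant. Degenerate cases are
defined, not left to chance: zero replicate variance with mean equal to the
null gives `p = 1`; zero variance with a discrepant mean gives `p = NaN`,
which is flagged and excluded from the FDR family (the family size is
reduced); codons absent from the genome with zero observed signal give
`p = 1`.

**Clustering.** Replicate profiles and the abundance profile are compared by
the distance `1 − r`, `r` the Pearson correlation, and clustered by
agglomerative hierarchical clustering. The agglomeration is implemented in
the package (complete, average and single linkage via Lance–Williams updates,
ties broken deterministically by smallest label index) so that its behaviour
is fully specified; the test suite cross-checks it against `stats::hclust`
cophenetic distances. Pearson correlation is invariant to per-profile affine
scaling, so clustering fractional profiles and count profiles is equivalent;
fractional profiles are used.

**Terminus blocks.** For each ORF, footprints whose 5' end lies between the
transcript 5' terminus and 5 nt downstream of the start codon's *first*
nucleotide are pooled, grouped by identical 5' start, and each group's depth
is its fraction of the pool. For internal starts the window keeps the same
shape with the terminus replaced by `start − leader_context` (default 40 nt).
Two summary metrics are emitted, because "covering the start" can reasonably
mean either: the fraction of pool footprints containing the start codon's
first nucleotide with their 5' end at or before it, and the fraction whose 5'
end is strictly inside the leader.

**Hydropathy.** GRAVY is the arithmetic mean of Kyte–Doolittle values over
the first 10 residues, with initiator recoding (AUA/AUU scored as Met)
applied before scoring, matching reference protein sequences. The initiator
is included in the 10 residues.

## Read-to-codon assignment and the observability mask

The assignment of a footprint to "its" codon is a genuine design choice. The
default is A-site assignment: each footprint increments the codon containing
the position `offset = 14` nt downstream of its 5' end (mid-footprint for
24–37 nt fragments, standard ribo-seq practice), so each read counts once and
profiles are interpretable as proportions. A `coverage` mode (every codon
fully inside the footprint) is retained for sensitivity analysis.

A-site assignment has a structural blind spot on leaderless transcripts:
codon `i` of an ORF with an `L`-nt leader can only sit in the A-site of a
footprint whose 5' end lies `3i + L − offset` nt into the transcript. When
`3i + L < offset` that 5' end would fall upstream of the transcript terminus,
which does not exist — such codons are *unobservable* no matter the data.
Comparing raw profiles against the full genomic abundance therefore builds in
false "depletion" at start-proximal codons (which are enriched for AUG/AUA/
AUU). The pause-testing default therefore applies an observability mask: the
codons with `3i + L < offset`, and codons overlapping another annotated CDS
in a different frame (where one read would be counted twice), are excluded
from *both* the footprint tally and the abundance profile, so both sides of
the test cover the same codon set. Excluding initiation-proximal and
overlapping regions is standard in codon dwell-time analyses. The unmasked,
whole-CDS comparison remains available (`use_observability_mask = FALSE`,
or `mask = NULL` in the functions).

**Denominators.** Three normalization policies are exposed. `parsed` (the
default for descriptive profiles) divides by the retained primary alignments
at parse time — the most literal reading of "total reads per replicate".
`filtered` divides by the footprints surviving the length filter. `cds`
divides by the reads assigned to the tallied (masked) codon set, so the
footprint fractions sum to 1 over exactly the same codon family as the
abundance profile they are tested against. The pause tests use `cds`: their
null hypothesis is equality of *compositions*, and under `parsed` any read
mass outside the family (initiation pileups, masked overlap codons) deflates
every fraction uniformly below its abundance value, biasing all 64 one-sample
tests in the same direction. Pearson-distance clustering is invariant to the
choice (a per-profile scalar). Duplicate reads are kept throughout, since
pileups at pause sites are the signal, not an artifact.

## What the synthetic-data generator emulates

`simulate_genome()` builds a compact mitochondrial-style reference whose
defaults mirror the real system: 13 ORFs (80–300 codons) on a ~14 kb genome,
leaders of 3, 1 and 0 nt (one each of 3 and 1; the rest leaderless, as in the
real transcriptome), one minus-strand ORF, one ORF with an incomplete stop
completed by polyadenylation, stop codons cycling through UAA/UAG/AGA/AGG so
every stop identity occurs, and one bicistronic unit whose downstream ORF
starts at an internal AUG displaced 40 nt from the upstream stop, out of
frame, with both frames kept free of premature stops.

`simulate_footprints()` draws each read from a two-component mixture:

* **elongation reads** pick an (ORF, codon) position with probability
  proportional to `expression × dwell_factor[codon identity]`, restricted to
  A-site-observable codons, and place the 5' end so the sampled codon sits at
  the A-site offset;
* **initiation reads** (mass controlled by `initiation_weight`, default 1)
  place their 5' end uniformly in the terminus window, reproducing the
  initiation-proximal pileups seen at 5' termini and internal starts.

Fragment lengths are drawn from a unimodal distribution over 24–37 nt
(discretized normal, mode 31 nt). Replicate counts are multinomial, or
Dirichlet-multinomial for overdispersion between biological replicates
(`dispersion`, `Inf` = multinomial). Reads never extend past the transcript
5' terminus; 3' extension past the CDS is allowed because mt-mRNAs carry
3' UTRs or poly(A) tails. Every draw is determined by the config seed.

What the generator does *not* emulate: sequencing error, adapter artifacts,
rRNA/tRNA contamination, non-uniform nuclease trimming, RNA structure, or
codon-autocorrelated dwell along a transcript. Passing calibration tests on
this generator therefore demonstrates that the statistical machinery is
correct under its stated model, not that real libraries satisfy that model.

## Calibration and verification choices

The test suite treats the spec-level properties as experiments with
pre-registered conditions:

* **Null calibration.** The null model is uniform dwell (all 64 factors 1)
  with no initiation pileup, 3 replicates × 100 000 reads on the default
  genome, 200 runs. Under the complete null every discovery is false, so the
  BH bound applies to the fraction of runs with any discovery; the one-sample
  procedure is required to stay within `0.05 + 2·SE(MC)` and the two-sample
  family-wise rate within 10%. The bicistronic overlap is present; its reads
  are excluded by the mask, which costs ~1% of the denominator uniformly —
  negligible against replicate noise (≈2.4% per codon at these depths).
* **Recovery.** A dwell factor of 3 on one codon (GAA), 3 × 500 000 reads,
  must be flagged enriched at `q < 0.05` in ≥95% of 50 runs; a configured
  factor of 5 (AGA) must be recovered within 10% from the occupancy/abundance
  ratio, normalized by the median per-codon ratio (the factor itself inflates
  the denominator by `4·n_AGA/N`, so the uncorrected ratio is biased low by
  about that much).
* **Clustering.** Two conditions differing by 2× dwell on five codons must
  separate at the top dendrogram split in ≥90% of 50 runs.
* **Terminus monotonicity.** The pooled start-coverage fraction over
  leaderless ORFs must increase strictly across initiation weights 0, 1, 5;
  at weight 0 it is exactly zero, because no admissible elongation footprint
  on a leaderless transcript reaches upstream of the start codon.

Problem sizes (200/200/50/50 runs at the stated depths) were chosen to keep
the whole verification suite within a few minutes on one CPU while holding
Monte-Carlo error well below the margins being tested.

## Numerical and interface conventions

* Coordinates are 0-based half-open internally; GFF3 (1-based inclusive) is
  converted at the boundary; BED is native. `five_prime_pos` is the genome
  coordinate of a footprint's 5'-most nucleotide in transcript orientation
  (the rightmost aligned base for '-' strand reads).
* Footprint lengths outside 15–50 nt are parse errors (sanity bound); the
  analysis filter is 24–37 nt.
* ORFs wrapping the circular origin are rejected (none of the thirteen real
  ORFs wrap); circularity is recorded on the reference container.
* Codon-usage tallies are computed with and without stop codons
  (`include_stops`, default `TRUE`); the incomplete terminal codon is
  excluded from usage because the genome does not contain its completed
  sequence.
* The genetic code is vertebrate mitochondrial (`transl_table` 2) with
  start-codon set {AUG, AUA, AUU}; both are overridable for testing.
* All randomness in the simulator flows from one integer seed; identical
  seeds give byte-identical BED output.

## Known limitations

* The A-site offset is fixed per library (no length-stratified offset
  calibration); with 24–37 nt fragments a single mid-footprint offset is a
  simplification.
* The one-sample test treats the abundance fraction as a known constant,
  ignoring its (tiny) finite-genome variance.
* Terminus block analysis reports 5'-start groups with per-group length
  histograms; it does not model initiation-complex footprint species
  explicitly.
* The pipeline analyses a single contig; nuclear-encoded transcripts and
  multi-contig references are out of scope.
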