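# mitoriboseq

Codon-level analysis of **mitoribosome profiling** data — ribosome-protected
mRNA fragments from the human mitochondrion, where 13 OXPHOS subunits are
translated by the 55S mitoribosome using only 22 tRNAs, recoded codons
(UGA→Trp, AGA/AGG→stop, AUA/AUU as initiators), largely leaderless mRNAs and
two bicistronic transcripts with internal start codons.

Given an annotated mitochondrial reference and aligned footprint libraries
(BED6 or SAM/BAM, 24–37 nt fragments), the package computes:

* **Codon occupancy statistics.** Per-replicate *fractional footprint
  profiles* (reads per codon identity ÷ total reads, A-site assignment at a
  fixed 5′ offset) are tested per codon against the genomic *fractional
  abundance profile* with two-tailed one-sample t-tests —
  `t = (x̄ − μ₀)/(s/√n)` — or between conditions with Welch two-sample
  t-tests, each 64-codon family corrected by Benjamini–Hochberg FDR
  (significant at `q < 0.05`).
* **5′-terminus footprint blocks.** Footprints starting between the
  transcript 5′ terminus and 5 nt past the start codon, grouped by identical
  5′ start; block depth = group fraction. Start-coverage summaries and raw
  per-nucleotide pileups for internal (bicistronic) initiation sites.
* **Per-ORF distributions.** Each gene/codon position's share of all
  CDS-assigned footprints in the library.
* **Profile clustering.** Replicates and the abundance profile compared by
  `1 − Pearson r` distance with agglomerative hierarchical clustering
  (complete/average/single linkage, implemented in-package and cross-checked
  against `hclust`).
* **Hydropathy.** Kyte–Doolittle GRAVY of the amino-terminal 10 residues,
  with initiator recoding (AUA/AUU → Met).
* **Synthetic data with ground truth.** A seeded generator that emulates the
  mitochondrial system — 13 ORFs, 0/1/3-nt leaders, a bicistronic overlap
  with an internal start displaced 40 nt from the upstream stop, incomplete
  stop codons, a minus-strand ORF, codon-dependent dwell, initiation-proximal
  pileups, 24–37 nt fragment lengths, multinomial or Dirichlet-multinomial
  replicates — so every stage of the pipeline is verifiable offline.

## Worked example

Simulate a control/mutant study in which the mutant mitoribosome dwells
2.5× longer on UUC (phenylalanine) codons, then recover that difference:

```r
library(mitoriboseq)

cfg <- simulation_config(
  seed = 20, reads_per_replicate = 200000,
  conditions = list(control = dwell_factors(),
                    mutant  = dwell_factors(UUC = 2.5)))
g    <- simulate_genome(cfg)        # <genome_reference> chrM_sim: 14000 bp (circular)
sim  <- simulate_footprints(cfg, g$ref, g$orfs)

mask  <- observable_codon_mask(g$orfs)            # A-site-observable codons
profs <- occupancy_profiles(sim$libraries, g$ref, g$orfs,
                            denominator = "cds", mask = mask)
res   <- two_sample_codon_tests(profs[, 1:3], profs[, 4:6])
subset(res, significant,
       select = c(codon, amino_acid, mean_control, mean_treated,
                  t_statistic, q_value, direction))
#>   codon amino_acid mean_control mean_treated t_statistic q_value direction
#> 2   UUC          F       0.0197       0.0454       -72.6 0.00806  depleted
```

Exactly one codon is called: UUC, at about half the mutant's occupancy in the
control (`direction` is relative to the first group), with `q = 0.008`. The
replicates also separate by condition at the top of the `1 − r` dendrogram:

```r
hc <- hierarchical_cluster(pearson_distance_matrix(profs))
top_split(hc)
#> control_rep1 control_rep2 control_rep3  mutant_rep1  mutant_rep2  mutant_rep3
#>            1            1            1            2            2            2
```

Initiation structure and leader-peptide hydropathy:

```r
orf <- g$orfs[g$orfs$leader_length == 0 & g$orfs$strand == "+", ][1, ]
sel <- select_terminal_footprints(sim$libraries[[1]], orf)
start_coverage_fraction(sel, orf)    # fraction of terminus-window footprints
#> [1] 0.134                          # that include the start codon's first nt

head(leader_hydropathy_table(g$ref, g$orfs), 4)
#>   gene_id    peptide gravy flag
#> 1   ORF01 MVCAVILFAG  2.71   ok
#> 2   ORF02 MKQRVWLDMH -0.77   ok
#> 3   ORF03 MRVDENMTVD -0.70   ok
#> 4   ORF04 MSGGTASFSL  0.64   ok
```

The same stages run end-to-end from files (FASTA + GFF3 + BED manifests)
through `run_pipeline("all", config)` or the thin CLI wrapper in
`inst/scripts/mitoriboseq-pipeline.R`; both write TSV artifacts, figures and
a machine-readable run log.

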