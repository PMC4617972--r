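# splicescreen

Junction-based alternative-splicing analysis for RNAi depletion screens.

## The problem

RNAi screens of splicing regulators knock down dozens of RNA-binding
proteins one at a time and read out the transcriptome by RNA-seq. The
analysis question is: *which splicing events does each protein regulate,
in which direction, and how do the regulators relate to one another?*
`splicescreen` implements that analysis for anyone working from
splice-junction read counts (BED files with the junction interval and its
read count) plus an exon annotation:

1. **Event discovery** — classifies eight event types from junction
   patterns and exon coordinates: cassette/skipped exons (SE), alternative
   5′/3′ splice sites (A5SS/A3SS), mutually exclusive exons (MXE),
   coordinate cassette exons (CSE), alternative first/last exons
   (AFE/ALE, with AFE gated on CAGE-supported transcription starts), and
   retained introns (RI). Annotated-but-unexpressed junctions that certify
   alternative use of an expressed junction are folded in; novel junctions
   are screened by the Shannon entropy of their read-start offsets.
2. **Quantification** — percent spliced in (PSI) from length-normalized
   isoform abundances:

   Ψ = a_incl / (a_incl + a_excl),  a = read count / isoform length

   with a 20-read expression cutoff per event and sample.
3. **Virtual reference** — a synthetic control built per event from
   cross-sample medians: reference inclusion count = median total count ×
   median inclusion ratio (and the exclusion analogue). Because any given
   event is affected by only a few knockdowns, the medians estimate the
   unperturbed state without relying on a separate control library.
4. **Differential splicing** — each knockdown's inclusion/exclusion counts
   are compared with the virtual reference by a two-sided Fisher's exact
   test; Benjamini-Hochberg correction is applied per condition and event
   type, and a call requires FDR < 0.05 **and** |ΔΨ| > 10 percentage
   points. Calls are tiered weak (10, 25], moderate (25, 50], strong
   (50, 100], and signed: reduced inclusion upon knockdown means the
   protein *activated* the exon, increased inclusion means it *repressed*
   it. Events with more than two isoforms are tested once per isoform and
   the isoform with the lowest corrected p-value is reported.
5. **Regulatory networks** — per-protein activation/repression bias
   (two-sided exact binomial, Bonferroni), coordinated vs. antagonistic
   regulator pairs (Fisher overlap test over jointly testable events,
   Bonferroni; shared targets partitioned by ΔΨ sign agreement), a
   cross-regulation matrix of regulators acting on each other's
   pre-mRNAs, and promoter-window ChIP-seq scoring of transcription-factor
   targets (−2000/+100 bp around the TSS) for secondary-effect checks.

A first-class synthetic-data generator plants all eight event types, plants
knockdown effects with beta-binomial counting noise, coregulated pairs and
cross-regulatory links, and keeps the ground truth, so every stage can be
validated by parameter recovery.

## Worked example

Simulate a small screen (100 events, 12 knockdowns × 2 replicates + 1
untreated library), write it as plain-text fixtures, and run the full
pipeline:

```r
library(splicescreen)

cfg <- sim_config(n_genes = 100, n_proteins = 12, depth_per_event = 200,
                  targets_per_protein = 10, seed = 42)
models <- generate_gene_models(cfg)
counts <- simulate_counts(models, cfg)
dir <- file.path(tempdir(), "demo")
write_fixtures(models, counts, dir)

out <- run_pipeline(
  list(junction_dir         = file.path(dir, "junctions"),
       annotation_gtf       = file.path(dir, "annotation.gtf"),
       annotation_junctions = file.path(dir, "annotation_junctions.bed"),
       metadata             = file.path(dir, "metadata.tsv"),
       offsets              = file.path(dir, "offsets.tsv"),
       region_counts        = file.path(dir, "region_counts.tsv"),
       outdir               = file.path(dir, "results")),
  run_config())

str(out$manifest$stages)
#> $ samples            : int 25
#> $ junctions_expressed: int 250
#> $ events_discovered  : int 100
#> $ events_expressed   : int 100
#> $ events_with_vref   : int 100
#> $ calls_tested       : int 1200
#> $ calls_significant  : int 136
#> $ events_affected    : int 75

head(out$calls[out$calls$significant, c("event_id", "condition",
     "delta_psi", "corrected_p", "magnitude", "direction")], 3)
#>                 event_id condition delta_psi corrected_p magnitude direction
#>   A3SS@chrS1:1400-1650:+       P01     -26.2    1.39e-23  moderate activated
#>   A3SS@chrS1:1400-1650:+       P09     -12.0    3.80e-04      weak activated
#> A3SS@chrS2:81400-81650:+       P07     -25.2    1.17e-20  moderate activated
```

All 100 planted events are discovered and quantifiable; 136 of the 1200
(event × knockdown) tests are significant, touching 75 events. Each call
reports the ΔΨ against the virtual reference in percentage points (here
P01 depletion drops inclusion by 26 points, so P01 activates that splice
site), the per-type BH-corrected p-value, and the magnitude tier. The
`results/` directory holds the same information as TSV tables (`events`,
`psi`, `vref`, `calls`, `bias`, `pairs`, `cross_matrix`) plus a JSON run
manifest; reruns on identical inputs are byte-identical.

A thin command-line wrapper is installed at
`inst/cli/splicescreen.R` (`simulate`, `run-all` subcommands).

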