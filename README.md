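# cryptic3ss

Detection and characterization of cryptic 3′ splice sites from RNA-seq
splice-junction tables.

Hotspot mutations in the splicing factor SF3B1 (most prominently K700E and
R625H) redirect the spliceosome to *cryptic* 3′ splice sites — unannotated
AG acceptors typically 10–24 nt upstream (intron-ward) of the canonical
acceptor. `cryptic3ss` implements the full computational workflow a
transcriptomics group needs to study this phenomenon from standard aligner
output, without touching reads or BAMs:

1. **Cryptic-site calling** from per-sample splice-junction count tables
   (the STAR `SJ.out.tab` dialect). Junctions with summed coverage < 50
   across samples are removed; a junction is a candidate cryptic site when
   exactly one of its two boundary bases matches an annotated donor or
   acceptor; it is paired with the fully annotated junction sharing its
   annotated end at minimum distance.
2. **Differential usage.** Per-sample percent-spliced-in,
   `PSI = cryptic / (cryptic + canonical)`, is compared between mutation
   groups with two-sided t-tests and Benjamini–Hochberg correction;
   differentially used cryptic 3′ss are those with `P < 0.05` located
   closer than 50 nt upstream of the canonical acceptor. Events are ranked
   by |ΔPSI| and split into mutation-preferred sets.
3. **Sequence context.** For cryptic, canonical, and control acceptors
   (introns with no cryptic usage), 110-nt windows (−100..+10 around the
   AG) are extracted in transcript orientation; per-position base
   composition is tested against controls with Fisher's exact test;
   maximal adenine runs (A, AA, AAA, AAAA≥4) within 50 nt upstream are
   counted and compared between mutation-preferred sets with a
   continuity-corrected Wilcoxon signed-rank test; six-mers in the 30 nt
   upstream are ranked and tested.
4. **Expression stage.** RPKM → log2 → sample-level quantile
   normalization → per-gene t-tests with BH; PCA (samples as
   observations, centred features) and Euclidean-distance hierarchical
   clustering of both expression and PSI matrices.
5. **Synthetic data with ground truth.** A generator builds multi-exon
   genes on both strands with polypyrimidine tracts and branch-point
   adenosines, plants cryptic AGs at known distances with group-wise PSI
   and class-dependent poly-A run density, simulates junction counts
   (negative-binomial depth, binomial cryptic usage) and NMD-coupled
   expression (group mean = baseline × (1 − efficiency × PSI)), and
   returns a truth registry so recovery can be scored exactly.

## Worked example

```r
library(cryptic3ss)

# a fully ground-truthed synthetic study: 1000 genes, 200 planted cryptic
# events, WT/K700E/R625H x 5 samples, junction depth ~ NegBin(100, 8)
ds  <- simulate_dataset(simulation_config(seed = 42), dir = "demo_data")

cfg <- pipeline_config(
  junction_files = ds$paths$junctions,
  gtf    = ds$paths$gtf,
  fasta  = ds$paths$fasta,
  counts = ds$paths$counts,
  groups_file = ds$paths$groups,
  out_dir = "demo_out")
res <- run_pipeline(cfg)

res$report$n_events
#> [1] 200
range(res$report$distance_histogram$distance)
#> [1] 10 24
head(res$top$event_id, 3)
#> [1] "chr12:24902-25181(+)" "chr3:55486-55755(+)"  "chr11:31405-31664(+)"
```

All 200 planted cryptic acceptors are detected, each at its exact planted
distance, and every distance falls in the 10–24 nt band the generator
emulates. `demo_out/` then contains the event table and BED track, the
differential-usage results, the preferred-set assignments and control
introns, the composition/Fisher/k-mer motif tables, the run-feature
tests, the normalized expression and DE tables, PCA scores, and a
machine-readable `report.json` + `manifest.json`.

ΔPSI in the result tables is `mean(PSI, group A) − mean(PSI, group B)`
for the named comparison (mutant-pooled vs WT, and R625H vs K700E);
`q` is the BH-adjusted p-value.

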