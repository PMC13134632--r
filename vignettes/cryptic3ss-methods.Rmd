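---
title: "Calling and characterizing cryptic 3' splice sites: models, parameters and design choices"
author: "cryptic3ss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterizing cryptic 3' splice sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cryptic3ss` analyses aberrant 3′ splice-site usage caused by
splicing-factor hotspot mutations (the SF3B1 K700E / R625H setting is the
motivating case). This vignette is the package's own account of the
models it implements, the parameters that matter, what the synthetic data
emulate, and the choices we made where the design was genuinely open.

## The splicing model

A *cryptic 3′ splice site* is an unannotated acceptor activated by a
mutant spliceosome, typically a short distance intron-ward of the
canonical acceptor it competes with. The observable signature in standard
RNA-seq is a splice junction that shares its donor with an annotated
intron but ends at a novel acceptor.

The caller works entirely on splice-junction count tables (the 9-column
`SJ.out.tab` dialect with 1-based first/last intronic-base coordinates
and strand codes 0/1/2):

1. **Coverage filter.** Junctions whose unique-read total summed across
   all samples is below `min_total_reads` (default 50) are removed.
   Totals exactly at the threshold are retained; only uniquely mapped
   reads are counted (the multi-mapped column is ignored as a
   conservative choice — the source tables do not say which column fed
   the original analyses).
2. **One-end-annotated classification.** Each stranded junction's donor
   and acceptor boundary bases are looked up in the annotation-derived,
   strand-matched site sets (on the + strand an intron's acceptor is its
   last base; the − strand flips this). A junction with exactly one
   annotated end is a candidate cryptic site; junctions with both ends
   novel are excluded, as are unstranded junctions (3′/5′ assignment
   requires strand; they stay in the table, flagged).
3. **Canonical pairing.** The candidates' partners are the fully
   annotated junctions in the same filtered table that share the novel
   junction's annotated end. The partner at minimum
   `|novel end − canonical end|` is chosen. Ties are broken toward the
   partner with larger total coverage, then smaller genomic coordinate —
   determinism where the method definition is silent.
4. **Side and direction.** The event is a 3′ss event when the novel end
   is an acceptor; *upstream* means the novel site lies 5′-ward of the
   canonical site in transcript orientation. 5′ss and downstream events
   are computed and reported but excluded from the downstream 3′ss
   analyses, which is where the biology of acceptor choice lives.

**PSI.** Per sample, `PSI = cryptic / (cryptic + canonical)` from the raw
unique-read counts of the event's two junctions, missing when the
denominator is zero. The denominator uses only the single paired
canonical junction, not every junction sharing the donor: PSI is defined
per cryptic/canonical pair, and pooling additional acceptors would mix
distinct events into one denominator. This is the simplest faithful
reading; it is a genuinely open choice and is isolated in
`compute_psi()` should a pooled variant ever be wanted.

## Differential usage

Group differences are tested per event on PSI values (not raw counts)
with a two-sided t-test; Welch's unequal-variance form is the default
because group variances differ systematically when usage differs
(binomial variance scales with PSI), with the pooled-variance form one
switch away. P-values are BH-adjusted. The selection rule for
differentially used cryptic 3′ss is `p < 0.05` (strict) **and** upstream
3′ss located closer than 50 nt (strict) to the canonical acceptor; both
thresholds are configuration values whose defaults are the method's
canonical operating point.

Degenerate inputs are resolved so that downstream conventions hold: two
zero-variance groups with equal means give `p = 1` (this is what makes
"no cryptic reads anywhere" introns have `p = 1`, the eligibility rule
for control introns), zero variance with unequal means gives the smallest
representable p; events with fewer than two usable PSI values in a group
are flagged and reported with missing p rather than dropped.

Event ranking is by descending |ΔPSI| with ties broken by ascending p
then event id. The R-preferred / K-preferred sets are the top
350 / 348 significant events by signed ΔPSI of the R-vs-K comparison
(sizes configurable; the defaults are the canonical set sizes). Control
introns are a seeded uniform sample (default 500) of annotated introns
with canonical coverage and no detected cryptic junction at their
acceptor.

## Sequence-context statistics

Windows span positions −100..−1 (intronic, with −2,−1 the acceptor AG)
and +1..+10 (exonic) in transcript orientation: 110 nt per site. On the
− strand the forward slice is reverse-complemented so every window reads
like a transcript. Windows running off a chromosome or containing N are
dropped with a logged count.

* **Composition and Fisher tracks.** Per-position A/C/G/T counts;
  at each position and base, a two-sided Fisher exact test of target vs
  control counts. P-values are reported raw as −log10 tracks against the
  0.05 line; per-position multiple-testing correction is deliberately off
  by default (a BH option exists) because the track is a descriptive
  visual device, not an inference procedure.
* **A-run features.** Within the stated region (default −50..−1; the AG
  itself is inside the region, taken literally — genuine AG bases almost
  never extend an A-run, and excising them would silently shift the
  coordinate frame) maximal adenine runs are classed as A (length 1),
  AA (2), AAA (3), AAAA (≥ 4). Counting maximal runs rather than
  overlapping k-mers keeps the four classes disjoint.
* **Group comparison.** The signed-rank comparison of two *event sets*
  needs a pairing; we pair by upstream position offset between the two
  groups' mean run-start-frequency tracks, which is the only alignment
  the data themselves provide. The test is two-sided with continuity
  correction, exact below 26 informative pairs, with zero differences
  dropped. A rank-sum alternative on per-window counts is available.
* **Six-mer enrichment.** Overlapping 6-mers in −30..−1, frequencies as
  count/total, Fisher vs control, ranked by target frequency.

## Expression stage

Counts are filtered on mean depth (default mean ≥ 1 across the cohort;
the removal threshold is never pinned by the method description, so it is
exposed), converted to RPKM (`count / (length/10³) / (library/10⁶)`),
log2-transformed with pseudocount 1, and quantile-normalized at the
sample level. Quantile normalization breaks ties by position order rather
than averaging them: tie-averaging violates the transformation's defining
property (identical sorted columns) and its idempotence on tied data, and
integer-count-derived matrices are full of ties. Differential expression
uses Student's pooled t (the stated test for this stage; Welch is a
switch), BH-adjusted, significant at `q < 0.05`.

PCA treats samples as observations with centred, unscaled features
(scaling is off because PSI and log-expression features are already on
comparable scales, and variance differences between events are signal).
Hierarchical clustering uses Euclidean distance; complete linkage is the
default (only the metric is pinned by the method description), with
average and Ward available.

## What the synthetic data emulate

The generator builds the statistical structure the analysis assumes,
with planted ground truth:

* 3-exon genes on both strands; exons 100–200 bp, introns 200–350 bp,
  packed 50 per chromosome with 100 bp spacers.
* Every canonical acceptor: AG preceded by a 25-nt T/C-biased
  polypyrimidine tract (T 0.55 / C 0.35) and a branch-point adenosine
  3–8 nt further upstream — the >20 bp pyrimidine stretch typical of
  constitutive acceptors.
* Event introns: a cryptic AG planted 10–24 nt (uniform) upstream of the
  canonical AG in the last intron. Between the two AGs the sequence is a
  weak pyrimidine stretch containing no G at all (so no competing AG),
  and no spurious AG survives within ~8 nt upstream of the planted one —
  acceptor ambiguity would otherwise make exact-distance recovery
  ill-posed.
* Poly-A planting: within −50..−3 of the cryptic AG, extra maximal A-runs
  of length 2–4 are inserted at a Poisson rate equal to the background
  run rate times (multiplier − 1); each inserted run is flanked by non-A
  guard bases so it stays maximal at its intended length. Multipliers:
  R-preferred 3×, K-preferred and shared 1.5×, matching the qualitative
  ordering (R ≫ K > control) without asserting any particular absolute
  frequency.
* Junction evidence is simulated at the junction-count level — the
  upstream alignment step is out of scope, so the SJ-table interface is
  the fidelity contract. Per intron and sample, depth ~ NegBin(mean 100,
  size 8); cryptic reads ~ Binomial(depth, group PSI); the canonical
  junction carries the annotated flag.
* Class PSI defaults: R-preferred (WT, K700E, R625H) =
  (0.02, 0.15, 0.40); K-preferred mirrored; shared (0.02, 0.30, 0.30);
  null 0.02 throughout.
* NMD coupling: an event gene's group mean is
  `baseline × (1 − efficiency × PSI_group)` with efficiency 0.8 —
  cryptic usage creates a premature termination codon and the misspliced
  fraction is largely degraded. Baselines are log-normal
  (meanlog log 300, sdlog 0.8, floored at 10); counts are NegBin with
  size 20, the moderate overdispersion of isogenic cell-line replicates.
* The default universe is 1000 genes carrying 200 events. The event
  count is the studied condition; the universe size keeps NMD-affected
  genes a minority (~20%) of the transcriptome, as they are in real
  cohorts — in a universe dominated by affected genes, library-size
  normalization itself cancels the per-gene depression, which is a
  compositional artifact of a too-small gene universe rather than a
  property of the method.

What the generator does **not** emulate: read-level errors and mapping
ambiguity, isoform complexity beyond one transcript per gene, covariate
structure (batch, cancer type), branch-point strength variation, and
genuine biological overdispersion of PSI beyond binomial sampling.
Passing recovery tests therefore demonstrates the pipeline's correctness
on its stated interfaces, not robustness to alignment artifacts or
cohort-level confounding.

## Numerical and testing choices

* Coordinates are 1-based inclusive end to end, the native convention of
  every format and library the package touches (SJ tables, GTF,
  Biostrings); only BED export converts to 0-based half-open, at the
  boundary.
* z-scores use the sample (n−1) standard deviation; constant rows map to
  zero.
* The type-I calibration experiment for the differential test uses null
  events at PSI 0.3 under the junction-count model: there PSI is
  effectively continuous and the t-test should hold its nominal level,
  which is the property being checked. At near-zero usage (the
  generator's default null class, PSI 0.02) cryptic counts are small
  integers and the t-test is conservative — a known property of t-tests
  on heavily discrete data, documented here rather than hidden in the
  calibration.
* Problem sizes used by the validation suite: 1000 random caller
  instances against a brute-force enumerator; the 1000-gene / 200-event
  default simulation for recovery, expression and clustering properties;
  2000 null events for calibration; 200 replicates of 350 + 348 windows
  for the run-feature comparison; exhaustive Fisher tables with margins
  up to 30 and signed-rank enumeration up to n = 12.

## Known limitations

* PSI uses a single canonical partner; genes with several strong
  acceptors sharing one donor will have slightly inflated PSI relative to
  a pooled definition.
* The caller cannot see cryptic acceptors whose junction also exists in
  the annotation (both ends annotated), nor fully novel junctions.
* The signed-rank pairing by position offset treats group-mean frequency
  tracks as the paired observations; it answers "do the positional
  profiles differ", not "do individual windows differ" (the rank-sum
  alternative answers the latter).
* Control-intron eligibility is "no cryptic junction detected at the
  acceptor", the operational version of p = 1; an intron with
  sub-threshold cryptic reads that were coverage-filtered can slip into
  the control set.
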