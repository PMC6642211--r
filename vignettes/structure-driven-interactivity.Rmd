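---
title: "Structure-driven protein interactivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-driven protein interactivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structint)
library(dplyr)
set.seed(1)
```

## The scientific question

How much does the secondary structure of an RNA tell us about how many
proteins it binds? `structint` implements the analysis chain needed to ask
that question quantitatively: per-nucleotide structure-probing evidence is
aggregated into a transcript-level *structural content*, CLIP peak tables are
reduced to per-transcript unique-binder counts, and the relationship between
the two is modelled by explicit functional forms. Around this core the
package carries three satellite analyses that probe the same relationship at
other scales: contact statistics of protein–RNA complexes in 3D, an
RNA-driven condensate-remodelling assay read out by label-free proteomics,
and amino-acid-scale property comparisons of the affected proteins.

Because the original measurements (transcriptome-wide probing, eCLIP,
crystal structures, mass spectrometry) are large external datasets, the
package ships a synthetic-data generator that emulates every input with
planted ground truth. All statistical behaviour documented here is what the
test suite actually measures on those synthetic cohorts.

## Structural content scores

**PARS-type profiles.** Nuclease probing yields, per nucleotide *i*, a
double-strand-specific read count V(i) and a single-strand-specific count
S(i). A nucleotide is called double-stranded when log10(V(i)/S(i)) > 0, and
the transcript's structural content is the fraction of such nucleotides:

content = (1/l) Σᵢ ϑ(log10(V(i)/S(i))), with ϑ(x) = 1 for x > 0, else 0.

Three numerical choices deserve comment:

* **The denominator l.** Transcripts with no reads at all are discarded, and
  by default l counts only *determined* nucleotides (V + S > 0). Counting
  undetermined positions as zeros would make the score fall with sequencing
  depth rather than with structure; the full-length denominator remains
  available via `denominator = "full"` for comparison with
  whole-length-normalized analyses.
* **Ties and zeros.** V = S (including 0/0) contributes 0, matching the
  strict "score higher than 0" reading; S = 0 with V > 0 is the infinite
  ratio limit and contributes 1. No pseudocount is added by default; a
  `pseudocount` argument exists because small-count ratios are noisy, but it
  changes calls only at V ≈ S.
* **The log transform.** The transcript-level ranking score is the *natural*
  log of the content: `log_content()`. The natural log is what makes the
  published score↔percentage anchor pairs consistent (exp(−1.3) ≈ 27%,
  exp(−2.8) ≈ 6%); base-10 would not.

**DMS-type profiles** are normalized to the transcript's maximum read count
and averaged over the positions present in the input; a reported zero-read
position counts as covered and pulls the mean down. Transcripts covered on
fewer than 10% of their length are excluded. High DMS reactivity marks
*unpaired* A/C nucleotides, so this score runs opposite to the PARS content;
the package never silently flips it — downstream preference classification
asks the caller for higher-is-more-structured scores, which for DMS means
negating.

**Predicted profiles** (per-nucleotide double-stranded propensities from any
external predictor) are reduced to the fraction of strictly positive scores.

UTR masking (`exclude_regions()`) restricts any profile to the coding span
before scoring, using 0-based half-open intervals.

## From CLIP peaks to binder counts

Input-normalized CLIP peaks are filtered at the stringent published
cut-offs, −log10(p) > 5 **and** log2(fold enrichment) > 3, both strict. The
enrichment cut-off is read as a plain log2 fold enrichment: selecting peaks
with *negative* log2 enrichment above 3 would pick depleted windows, the
opposite of a stringent selection. Binder counts are distinct-RBP tallies
with cell lines merged by union, so a protein detected in two cell lines
counts once.

An RBP's structure preference (`classify_preference()`) compares the content
scores of its targets against a background transcriptome with a two-sided
Mann–Whitney U test at α = 0.01 (the KS test is available via `test =
"ks"`). The choice of test is ours: the source analyses name both
Wilcoxon/Mann–Whitney and KS for distribution comparisons without tying one
to this step. Set-overlap significance (`empirical_overlap_p()`) is a
permutation test drawing 1000 random binder sets of matched size, with the
add-one estimator so a finite sample never reports exactly zero.

## The structure-to-binders fits

Two functional forms link content x to binder count y:

* exponential: y = exp(α + βx)
* reciprocal: y = 1/(α + βx)

Both are fit by unweighted least squares on the original y scale —
the published analyses name only the functional forms, so the least
committal loss is used — initialized from the linearized ordinary
regressions (log(y+1) on x, and 1/y on x) and refined by
Levenberg–Marquardt iteration on the analytic Jacobian. The refined solution
never has a larger residual sum of squares than its initializer, and
noiseless data is recovered to numerical precision (the suite checks 1e−6).
For count data a `loss = "poisson"` flag fits the exponential form by a
log-link Poisson GLM instead. The reciprocal fit refuses solutions whose
denominator α + βx changes sign inside the observed x range, since the model
is meaningless across that pole. On synthetic cohorts generated with the
published coefficients (exponential α = −0.75, β = 0.67 with Poisson counts
at n = 5000; reciprocal α = 2.60, β = 87.36 with Gaussian noise sd 0.005 at
n = 1000) the mean recovered coefficients over 10 replicates land within
±0.1 (and ±5 for the reciprocal slope) of truth; `scripts/acceptance.R`
recomputes exactly this.

```{r fit-example}
d <- tibble::tibble(x = runif(2000))
d$y <- rpois(2000, exp(-0.75 + 0.67 * d$x))
fit <- fit_binder_model(d, model = "exponential")
tidy(fit)
```

## Sequence-similarity clusters

`cluster_sequences()` mirrors the representative-first greedy strategy of
CD-HIT-style tools: sequences sorted by length (ties lexicographic), each
joining the first cluster whose *founding* sequence it matches at ≥ 85%
identity, else founding its own. Identity is matches over global-alignment
length (match 1, mismatch 0, affine gaps −1/−0.5). This is not CD-HIT's
exact word-filtered identity — the analysis only needs a consistent,
deterministic ≥ 0.85 criterion, and the threshold is exposed. Per-cluster
Pearson correlations between structure score and binder count
(`paralog_correlation()`) summarize to the fraction of clusters with
negative correlation; with DMS-scale scores a negative correlation means the
more structured family member binds more proteins.

## 3D contact statistics

From each complex we count phosphate–phosphate pairs of distinct nucleotides
under 7 Å (internal, a proxy for RNA structure) and phosphate–Cα cross-pairs
under 7 Å (external, the protein interface), both with strict inequality,
and normalize:

* internal score = log2((1 + n_internal) / L_RNA²)
* external score = log2((1 + n_external) / (L_RNA · L_protein))

Pairs are unordered and counted once; sequence-adjacent phosphates are *not*
excluded (they sit under 7 Å and no exclusion is stated in the source
analysis); residues missing a phosphate still count toward the chain length.
PDB files are parsed with bio3d: first model, highest-occupancy alternate
location (first on ties), HETATM skipped, and every RNA×protein chain pair
reported as its own complex. The implementations are checked against literal
O(n²) double loops and under rigid motions.

## The condensate assay

The LFQ matrix covers three conditions (background, HS-RNA, LS-RNA) × 4
replicates. Proteins are quantifiable with ≥ 3 valid values in at least one
condition. Differential testing is Welch's t on log2 intensities (LFQ
intensities are log-normal-like and unequal variances are the safe default;
Student's and a raw-intensity mode are flags), with the log-ratio reported in
log2 — the published tier thresholds (0.15 / 0.30 / 1) do not name their log
base, so base 2 is assumed and configurable. Missing values are never
imputed; a protein needs two valid values per side to be testable.
Classification: released = significant (−log10 p > 1.3) and down; kept =
significant and up; the rest static. Stringency tiers bucket the doubly
non-significant proteins by |log ratio| under both RNAs and are nested by
construction. ROC AUC uses the rank-sum formulation with ties credited 1/2,
and is invariant to monotone transforms of the score.

## The synthetic-data generator

The generator's defaults define the study conditions the tests measure:

* **Probing reads**: Poisson per nucleotide with a 0.9/0.1 rate split
  between the state-concordant and discordant channel at depth 50 — the
  simplest model matching the count nature of probing data. It does not
  emulate coverage gradients, ligation bias, or transcript-abundance
  effects, so passing tests show score-aggregation correctness, not
  robustness to real probing artifacts.
* **Binder counts**: distinct RBPs sampled without replacement per
  transcript, count ~ Poisson(f(x)). The published analyses state no noise
  model around the fitted curves; Poisson is this package's choice, made
  once. Decoy sub-threshold peaks and cross-cell-line duplicates exercise
  filtering and union counting.
* **Complexes**: both chains placed uniformly in a box whose volume shrinks
  with a per-complex latent compaction factor, coupling internal and
  external density (dataset correlation > 0.5 at n = 200 in the suite).
  These are geometric toys: no backbone connectivity or sterics.
* **LFQ**: log2 baselines U(22, 30), replicate noise sd 0.05, planted
  2-fold released/kept shifts in the HS condition only, 10% missingness
  applied independently per cell. The released-vs-rest interaction score is
  normal with shift √2·Φ⁻¹(AUC), which gives the planted AUC exactly in
  expectation.
* **Paralogs**: point-mutated copies of a cluster seed at 5% per position —
  identity is controlled directly — with binder counts strictly monotone in
  the structure score per cluster so the planted correlation sign is
  guaranteed.

Problem sizes used by the suite (cohorts of 500–1000 transcripts at depth
50, 200 complexes, 500–1000 proteins, 100 clusters, 10 fit replicates) were
chosen so each planted quantity is recoverable within its stated statistical
tolerance at desk scale.

## Known limitations

* The content score treats nucleotides independently; no smoothing across
  positions.
* `cluster_sequences()` is O(n²) in alignments and intended for the
  paralog-analysis scale (tens to hundreds of sequences), not
  transcriptome-scale clustering.
* The condensate analysis starts from a finished LFQ matrix; raw
  mass-spectrometry processing is out of scope, as are peak calling,
  genome-to-transcript mapping, structure prediction, and the external
  interaction predictors whose scores the package only consumes.
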