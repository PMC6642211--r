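# structint

**Structure-driven protein interactivity of RNA.**

`structint` is an R package for quantifying the relationship between the
secondary-structure content of RNA molecules and the number of proteins they
interact with. The more double-stranded regions a transcript carries, the
more distinct RNA-binding proteins (RBPs) tend to contact it; this package
implements the full analysis chain behind that observation, for anyone
working with structure-probing data (PARS/DMS-type), CLIP peak tables,
protein–RNA complex structures, or RNA-driven condensate proteomics.

## What it computes

* **Structural content** (`structure_content()` and friends): per-transcript
  fraction of double-stranded nucleotides from paired nuclease read counts —
  content = (1/l) Σᵢ ϑ(log10(V(i)/S(i))) with ϑ(x) = 1 for x > 0 — plus the
  DMS (normalize-to-max, inverted convention) and predicted-score variants,
  natural-log ranking scores, and UTR masking.
* **Binder counts** (`filter_peaks()`, `count_binders()`): CLIP peaks kept at
  −log10 p > 5 and log2 fold-enrichment > 3, then distinct-RBP tallies per
  transcript; per-RBP structure preference calls and permutation-based
  binder-set overlap p-values.
* **The structure→binders fits** (`fit_binder_model()`): least-squares fits
  of y = exp(α + βx) and y = 1/(α + βx) with broom-style `tidy()` /
  `glance()` and `autoplot()` methods.
* **3D contact statistics** (`contact_scores()`): phosphate–phosphate and
  phosphate–Cα contacts under 7 Å from PDB files, normalized as
  log2((1 + n)/L²) and log2((1 + n)/(L·L_protein)), and their dataset-level
  Pearson correlation.
* **Condensate assay** (`lfq_differential()`, `classify_release()`,
  `stringency_tiers()`, `roc_auc()`): quantifiability filtering of an LFQ
  matrix, Welch tests of RNA vs background, released/kept/static calls,
  nested stringency tiers, and rank-sum ROC evaluation of interaction
  scores.
* **Protein properties** (`score_sequences()`): Grantham polarity,
  Chou–Fasman helix and Kyte–Doolittle scales with KS set comparisons.
* **Synthetic data** (`simulate_*()`): generators for every input above with
  planted ground truth (true double-stranded fractions, a planted
  binder-count law, coupled contact densities, planted released/kept labels
  and AUC), making the whole pipeline testable offline.

## Worked example

Simulate a probing cohort, score it, plant a binder-count law on the scores,
and recover the law:

```r
library(structint)
library(dplyr)

sim <- simulate_structure_profiles(
  n_transcripts = 300, read_depth = 50, length_range = c(200, 500), seed = 42
)
scores <- pars_content(sim$pars)
head(scores, 3)
#> # A tibble: 3 x 4
#>   transcript_id content log_content n_determined
#>   <chr>           <dbl>       <dbl>        <int>
#> 1 tx0001          0.218      -1.52           248
#> 2 tx0002          0.520      -0.654          352
#> 3 tx0003          0.821      -0.198          273

peaks <- simulate_clip_peaks(scores, alpha = -0.75, beta = 0.67, seed = 43)
counts <- filter_peaks(peaks) |>
  count_binders(transcript_ids = scores$transcript_id)

d <- inner_join(scores, counts, by = "transcript_id")
fit <- fit_binder_model(d, x = "content", y = "n_binders", model = "exponential")
fit
#> Binder-count fit: y = exp(alpha + beta * x)
#>   alpha = -0.6691 (se 0.1738), beta = 0.7162 (se 0.2708)
#>   n = 300, rss = 229.7, loss = ls
```

The planted coefficients (α = −0.75, β = 0.67) are recovered within one
standard error from 300 transcripts. `tidy(fit)` returns the coefficient
table, `autoplot(fit)` draws the data with the fitted curve.

The 3D side of the same relationship, on synthetic complexes with coupled
contact densities:

```r
cplx <- simulate_complexes(200, seed = 44)
sc <- contact_scores(cplx$coordinates)
dataset_correlation(sc)
#> [1] 0.89
```

A positive correlation between the internal (intra-RNA) and external
(RNA–protein) contact scores says that, complex by complex, more structured
RNA comes with a larger protein interface.

## Documentation

The methods vignette
(`vignettes/structure-driven-interactivity.Rmd`) describes the models, the
numerical choices (denominators, log bases, tie handling, fit
initialization), what the synthetic generators do and do not emulate, and
the package's limitations.
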