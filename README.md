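# hetphos

Kinase-specific phosphorylation-site prediction from heterogeneous features.

## What problem this package addresses

Most phosphorylation-site predictors look only at the short peptide around a
candidate serine/threonine.  But whether a kinase family actually
phosphorylates a residue also depends on protein-level context: kinase and
substrate must share a compartment, often interact, and a family's substrates
cluster in pathways and functions.  hetphos is for computational biologists
who want to combine both levels: it selects annotation terms (pathways,
GO-style ontology terms, domains, interaction partners) that are over- or
under-represented among a kinase family's known substrates, prioritizes
candidate proteins with a redundancy-weighted log-odds score over those
terms, and classifies individual S/T peptide windows with an RBF-kernel SVM
over sequence, structure and functional features.

The core statistics:

* **Term selection** — exact two-sided hypergeometric test (minimum-
  likelihood convention) of each term's count *k* among *n* substrates
  against *K* of *N* proteome proteins, Bonferroni-corrected per namespace,
  significant at corrected p < 1e-2.
* **Protein score** — for selected binary features *x₁…xₙ*,

  S = Σᵢ (1/wᵢ) · ln( f(xᵢ) / g(xᵢ) ),

  with *f* the Laplace-smoothed feature probability among substrates, *g*
  in the whole proteome, and wᵢ = 1 + Σ_{r≠i} (1 − d_J(cᵢ, c_r)) a Jaccard
  redundancy weight so correlated features share, rather than double, their
  contribution.  Proteins scoring above the median substrate score form the
  scan candidate set.
* **Site classifier** — 9-mer windows encoded as 20 bits/residue (sequence)
  + 1 coil flag + 7 accessibility bits per residue (252 bits), concatenated
  with one indicator per selected term, classified by libSVM (RBF kernel)
  with per-fold feature re-selection inside repeated five-fold
  cross-validation and a 70%-identity homology guard on positives and
  sampled negatives.

A seeded synthetic-data generator plants a sequence motif at true sites and
enriched/depleted annotation terms among substrates, so the whole pipeline
is testable and calibratable without any external database.

## Worked example

```r
library(hetphos)
library(dplyr)

cfg <- synth_config(seed = 2024)   # 50 substrates x 2 sites, 500 background
ds  <- simulate_dataset(cfg)
ds
#> <phospho_dataset>
#>   proteins:    550
#>   sites:      100 (families: CDK)
#>   namespaces:  kegg, go_bp, go_cc, go_mf, pfam, interpro, string_ppi
#>   structure:   165000 records

enr <- enrich_dataset(ds, "CDK")   # two-sided hypergeometric + Bonferroni
head(enr, 4)
#> # A tibble: 4 x 9
#>   namespace term_id         k     n     K     N    p_raw p_corrected direction
#> 1 kegg      kegg:T0002     30    50    66   550 2.31e-18    6.94e-17 over
#> 2 kegg      kegg:T0003     24    50    61   550 1.98e-12    5.94e-11 over
#> 3 kegg      kegg:T0001     23    50    76   550 4.34e- 9    1.30e- 7 over
#> 4 go_bp     go_bp:T0002    30    50    77   550 5.65e-16    1.70e-14 over
```

21 terms come out significant (the generator planted 21 enriched and 14
depleted terms; the weak depleted signal is mostly below the radar — see the
vignette).  Score every protein and compare distributions:

```r
model  <- fit_logodds(ds, "CDK", features = enr)
scores <- score_proteins(ds, model)
ks_compare(scores$score[scores$is_substrate],
           scores$score[!scores$is_substrate])
#> # A tibble: 1 x 4
#>   statistic p_value   n_x   n_y
#> 1     0.978       0    50   500
plot_score_distributions(scores)   # substrate vs background histograms
```

The KS statistic of 0.98 says substrate and background score distributions
barely overlap on this strongly planted dataset.  Cross-validate feature
groups (here 5 repetitions for speed; each group = sequence+structure plus
one namespace's significant terms):

```r
cv <- run_cv(ds, "CDK", reps = 5, seed = 1,
             groups = c("all", "sequence", "cc", "string"))
cv
#> <phospho_cv> family: CDK | split: site | 5 folds x 5 reps | 100 pos / 100 neg
#>   group     mean    sd
#> 1 all       94.5 0.612
#> 2 sequence  89.7 0.570
#> 3 cc        88.7 0.975
#> 4 string    88.8 1.89
#> minus (all - sequence): 4.8
```

`minus` is the headline contrast: adding all functional features lifts mean
accuracy from 89.7% to 94.5% here.  `autoplot(cv)` draws the per-group bar
chart, and `tidy()`/`glance()` give tabular summaries of every result type.
The full chain — simulate → enrich → score → cv → train → scan — runs with
`run_pipeline(out_dir, cfg)`, writing every intermediate as TSV; a thin
command-line front end lives at `inst/cli/hetphos.R`.

## Package layout

* `R/data-io.R` — FASTA/TSV readers and writers, feature matrices, the
  validated dataset container
* `R/simulate.R` — the synthetic-data generator and its null twin
* `R/windows.R` — peptide windows, binary encodings, identity and homology
  filtering, background pool, negative sampling
* `R/enrichment.R` — hypergeometric tests, Bonferroni, term selection
* `R/scoring.R` — probability estimation, Jaccard weights, protein scores,
  KS comparison, candidate set
* `R/cv.R` — feature groups, repeated leakage-safe cross-validation, final
  model training
* `R/scan.R` — proteome scan and the end-to-end pipeline
* `vignettes/hetphos-methods.Rmd` — the model, its assumptions, numerical
  choices, and what the synthetic calibration does and does not show
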