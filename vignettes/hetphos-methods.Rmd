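---
title: "Predicting kinase-specific phosphorylation sites from heterogeneous features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting kinase-specific phosphorylation sites from heterogeneous features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(hetphos)
library(dplyr)
```

## The problem and the model

A kinase family phosphorylates serine/threonine residues of its substrate
proteins.  The peptide immediately around a site carries a recognizable
consensus signal, but it does not determine phosphorylation on its own:
kinase and substrate must also co-localize, often interact directly or through
scaffolds, and substrates of one family tend to share pathways and functions.
hetphos therefore works at two levels:

1. **Protein level.**  Annotation terms (pathways, ontology terms, domains,
   interaction partners) that are over- or under-represented among a family's
   known substrates are detected by exact two-sided hypergeometric tests
   against the whole proteome, Bonferroni-corrected per namespace, at
   corrected $\alpha = 10^{-2}$.  Candidate proteins are then ranked by a
   weighted log-odds score over the selected binary features
   $x_1, \dots, x_n$:
   $$ S(\text{protein}) \;=\; \sum_{i=1}^{n} \frac{1}{w_i}
      \ln \frac{f(x_i)}{g(x_i)}, $$
   where $f$ is the feature-value probability among known substrates, $g$
   the probability in the whole proteome (both Laplace-smoothed), and
   $w_i = 1 + \sum_{r \neq i} \big(1 - d_J(\mathbf{c}_i, \mathbf{c}_r)\big)$
   is a redundancy weight built from Jaccard distances $d_J$ between the
   features' incidence columns $\mathbf{c}$ over the proteome.  Correlated
   features (say, a pathway and the process term describing it) share their
   weight instead of being double counted.

2. **Site level.**  Every candidate 9-mer window (center residue, offsets
   $-4..+4$) is encoded as a binary vector — 20 bits per residue for the
   sequence, 1 coil flag and a 7-bit solvent-accessibility one-hot per
   residue, 252 bits in all — concatenated with one indicator per selected
   functional term of the window's source protein, and classified by an
   RBF-kernel SVM trained on known sites versus background windows.

The proteome scan combines the two: proteins scoring above the **median**
substrate score form the candidate set, and every non-known S/T window in a
candidate is classified; positive decision values are reported as predicted
sites.

## Encodings and numerical choices

* **Residue order.**  One-hot columns follow the fixed alphabetical order
  `ACDEFGHIKLMNPQRSTVWY` (`aa_alphabet()`).  A column permutation cannot
  change any statistic or kernel value, so the order is a pure convention.
* **Unknowns and padding.**  `X` (unknown residue, or window overrun at a
  terminus) encodes as an all-zero 20-bit block.  In identity computations
  `X` matches nothing, including another `X`.
* **Accessibility bins.**  Scores arrive on a 0 (buried) to 9 (exposed)
  scale; candidate residues essentially never exceed 6, so the encoding uses
  7 bins with the bit at index `min(score, 6)` — score 0 sets bit 0, scores
  7–9 clamp into the top bin.  Missing structure records degrade to all-zero
  structure bits with a warning.
* **Two-sided rule.**  `two_sided_p()` uses the minimum-likelihood
  convention standard for exact tests: the sum of all support outcomes no
  more likely than the observed one, with a relative tie tolerance of
  $10^{-7}$ guarding equal-mass outcomes against floating-point noise.  A
  doubled-smaller-tail alternative is available (`tail = "double"`).
* **Bonferroni scope.**  The test count $m$ is per namespace and per family,
  because namespaces enter the classifier as separate feature groups;
  terms absent from the background ($K = 0$) are untestable and excluded
  from $m$.  Pooling across namespaces would only rescale the cutoff.
* **Smoothing.**  $f$ and $g$ use pseudocount 1
  ($f_1 = (k + 1)/(n + 2)$), keeping every probability strictly inside
  $(0, 1)$ so log-odds are always finite.  Unsmoothed estimates would put
  infinite weight on features never seen in one class.
* **Self-inclusive weights.**  $w_i$ includes the feature's self-similarity
  of 1, so $w_i \ge 1$ always and a lone feature has weight exactly 1.
  Duplicating a feature column splits its weight across the pair
  ($w = 2$ each), leaving the total score unchanged.  This invariance is
  exact when the duplicated feature shares no support with the remaining
  features; for correlated features a duplicate also nudges the *other*
  features' weights (each gains one extra similarity term), so the total
  moves slightly — the designed behavior of a pairwise redundancy weight,
  not an error.
* **Logarithm base.**  Natural log; only relative order matters downstream.
* **Homology reduction.**  Greedy, first-come-first-kept: a window is
  dropped iff its ungapped identity to an already-kept window exceeds 0.7.
  The same guard applies to sampled negatives.  Filtering acts on 9-mer
  windows (site-level sets); identity exactly 0.7 is unreachable for 9-mers
  ($k/9 \neq 0.7$), so the boundary is moot in practice.
* **Classifier.**  `e1071::svm` (libSVM) with the radial-basis-function
  kernel, cost 1 and $\gamma = 1/p$ for $p$ features; binary inputs are not
  rescaled.  No hyperparameter search — the comparison across feature groups
  holds the classifier fixed and varies only the features.
* **Decision threshold.**  A scanned window is called a site at decision
  value 0 (the margin), the natural zero of a binary SVM.

## Cross-validation protocol

`run_cv()` repeats five-fold cross-validation `reps` times.  Within each
repetition the positives are the family's homology-filtered site windows and
the negatives an equal-count, homology-guarded uniform sample from the
background pool (every S/T window in the proteome minus known sites).  Two
split modes exist: `site` splits windows directly (each fold then holds
equally many positives and negatives by construction), while `protein`
assigns each *source protein* to one fold — a protein contributing both
positive sites and negative windows stays on one side of every split, so
fold class sizes are balanced only in expectation.  Protein-level splits are
the stricter protocol when several sites share a protein.

Functional terms are re-selected **inside every training fold** from the
training-fold substrates only.  This is the leakage guard: a term carried
only by test-fold substrates can never enter the feature set of that fold,
which the test suite asserts directly with a planted poison term.

Accuracy is the percentage of correct predictions over the pooled positive
and negative test windows; the headline contrast is `minus`, the all-features
accuracy minus the sequence-only accuracy.  Negatives are redrawn each
repetition by default (`resample_negatives = FALSE` fixes one draw).
Repetition $r$ runs on the derived child seed `seed + r`, so reports are
reproducible and individual repetitions can be re-run in isolation.

## What the synthetic generator emulates

`simulate_dataset()` produces data with exactly the two kinds of structure
the method exploits, and nothing else:

* substrate proteins carry planted true sites whose $-4..+4$ windows follow
  a position-specific motif mixed with uniform residues at `motif_strength`
  (default: proline at $+1$ with strength 0.8 — a proline-directed,
  CDK/MAPK-like preference);
* annotation terms are independent Bernoulli flags at a background rate
  (default 0.1), with enriched/depleted terms tilted for substrates through
  an odds ratio, $p' = \mathrm{OR}\,p / (1 - p + \mathrm{OR}\,p)$, which
  keeps the background rate interpretable and the hypergeometric alternative
  well defined (defaults: three terms at OR 8 and two at OR 1/8 in each of
  seven namespaces);
* structure labels are uniform over {H, E, C} and accessibility uniform over
  0..6 for every residue — deliberately uninformative, so structure bits act
  as realistic ballast rather than signal.

The defaults describe the calibration conditions used throughout the tests:
50 substrates with 2 sites each (100 positive sites) over a 500-protein
background of length 300.  Sites are planted at least 5 residues from the
termini and 9 apart, so training windows are unpadded and non-overlapping
(padding behavior is tested separately).  Each component — sequences, sites,
each namespace, structure — draws from its own derived seed stream, so adding
a namespace leaves the sequences untouched, and the whole dataset is a pure
function of configuration plus seed.  `null_dataset()` forces all odds ratios
to 1 and the motif strength to 0, giving a matched no-signal control.

What the generator does **not** emulate: realistic protein-length
distributions, ontology structure (terms are independent, real GO terms are
nested), annotation sparsity patterns, interaction-network topology, or
compositional sequence bias.  Tests passing on this generator therefore show
that the machinery is correct and calibrated — not that any particular
accuracy will be attained on real proteomes.

### The scan-study configuration

One generator setting deserves its own account.  Under the calibration
defaults the 21 planted terms separate substrate-like proteins from the
background almost perfectly; the above-median candidate set then consists
exactly of proteins whose functional block looks substrate-like, and every
window on them inherits that protein-level evidence — within-protein site
discrimination collapses by construction, and the fraction of predicted
windows approaches 1.  Real proteome scans operate in the opposite regime:
a sharp consensus motif, modest functional signal, and sparse predictions
(on the order of 0.1–5% of candidate windows).  The scan-recovery
experiments therefore use a *scan-study configuration*: a two-offset motif
(P at $+1$, R at $+3$) at strength 0.9 and a single enriched term in each of
three namespaces.  Half the substrates are hidden from training; they keep
their planted sites and annotations, so the score stage must shortlist them
and the classifier must find their sites.  Pooled over 10 seeds this yields
recall near 1 at roughly 5-fold enrichment of true sites among predictions
relative to the candidate-window base rate.

## Problem sizes used by the tests and the acceptance script

Monte-Carlo checks run at sizes chosen to estimate each quantity stably:
200 null datasets (50 substrates / 500 background / 200 terms) for the
family-wise error rate; 30 seeds for planted-term recovery at OR 10; 10
repetitions of five-fold CV on the 100-positive calibration dataset and its
null twin for the feature-group contrast; 50 planted and 50 null seeds for
the score-distribution KS comparison; 10 seeds for the hold-out scan.
The exact two-sided test is verified against full-support enumeration for
every parameter combination with $N \le 25$.

## Known limitations

* Negative windows may contain unreported true sites; the background-pool
  construction accepts this dilution, as the non-sites dominate.
* The score assumes feature independence up to pairwise redundancy; the
  Jaccard weight corrects double counting but not higher-order structure.
* Protein-level scores are shared by all windows of a protein, so the scan's
  within-protein ranking rests entirely on the sequence/structure block.
* With very small families (tens of sites) the `string_ppi` namespace can
  select many partner terms and overfit the classifier; the per-group CV
  report makes this visible rather than preventing it.
* The identity filter is ungapped and window-local; full-length homologs
  sharing no 9-mer above 70% identity are not removed.
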