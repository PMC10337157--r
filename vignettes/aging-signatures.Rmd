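---
title: "Identifying multi-tissue aging gene-expression signatures with agesig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying multi-tissue aging gene-expression signatures with agesig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agesig)
library(dplyr)
```

## Overview

`agesig` analyses bulk RNA-seq time courses of aging: many age groups across
the lifespan (months), several tissues, one or two species. Its question is
not merely *which* genes change with age but *how* — steadily, or switch-like
around a particular age — and what that implies at the pathway, cross-species
and regulator level. The pipeline has five stages, each exposed as ordinary
tidyverse-style functions and orchestrated by `run_pipeline()`.

This vignette explains the models, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate,
the numerical choices, and the design decisions that were genuinely open.

## The models

### Differential-expression gating

Counts are normalised to prior-damped log2 counts-per-million,
`log2((count + prior) / (libsize + 2 prior) * 1e6)` with `prior = 0.5`
(`log2_cpm()`). This is the de-facto standard log-CPM transform: the prior
keeps zeros finite and damps the variance of weakly expressed genes. No
between-sample scale normalisation beyond library size is applied; the
simulated data have no composition biases that would require one, and a
scale-factor hook can be added where real data do.

Each age is contrasted against the youngest (reference) age with a
two-sample comparison on log2-CPM (`fit_contrast()`). Gene-wise variances
are moderated by an empirical-Bayes squeeze (`squeeze_var()`): the prior
degrees of freedom and prior variance are estimated by method of moments on
the log sample variances (matching the scaled-F marginal of the standard
hierarchical model for gene variances), and the moderated t-statistic gains
the prior degrees of freedom. The test suite cross-checks this estimator
against limma's implementation of the same model.

A gene is differentially expressed (DE) when, at *any* age versus the
reference, `|log2 FC| > log2(1.5)` and the Bonferroni-adjusted p falls
below `de_alpha = 0.05` (`call_de()`). Both gates are deliberate bluntness:
the DE universe is only a pre-filter for trajectory fitting, so it favours
specificity. The Bonferroni family defaults to genes-within-contrast
(`de_family = "per_contrast"`); a `"global"` genes-by-contrasts family is
available because the family convention is a genuine choice — published
analyses of this design do not pin it down, and per-contrast is both the
laxer and the more interpretable reading of "adjusted p at that age".
The significance threshold itself is a parameter because reasonable
analyses have used 0.05 or 0.01 here; 0.05 is the default.

### Trajectory classification

Each DE gene's log2-CPM over age *t* is fit with three models
(`fit_trajectory()`):

* null: a constant (the grand mean; closed form),
* linear: ordinary least squares on *t* (closed form),
* 4-parameter logistic: `f(t) = A + (D - A) / (1 + exp(-b (t - c)))`.

The logistic parameterisation is constrained to `D >= A`, which makes the
sign of the Hill coefficient `b` the sole carrier of direction (a curve
with `A > D` is identical to the swapped curve with `-b`, so the constraint
costs nothing). The inflection `c` is constrained to the observed age
range: an out-of-range inflection is observationally indistinguishable from
a line or a constant, and the BIC comparison should arbitrate those cases,
not the optimizer.

Model choice uses `BIC = n ln(RSS/n) + k ln(n)` with `k = 1, 2, 4`. The
common noise variance is excluded from `k`: only BIC *differences* matter
and the variance term is shared by all three models. A gene is age-related
when the better of the linear and logistic BICs undercuts the null BIC by
more than `evidence_cutoff = 6` — a strong-evidence threshold on the BIC
scale — and is then labelled linear unless the logistic wins by more than
`linear_priority = 2`, giving the simpler model priority
(`select_model()`). Logistic genes are staged by their inflection age:
early before 12 months, mid from 12 to 21, late after 21
(`stage_logistic()`). The mid interval is closed on both ends; the
boundary convention is not externally fixed, so ties at exactly 12 or 21
months go to "mid".

### Pathway enrichment and the cross-tissue filter

Each trajectory class's gene list is tested per stratum against pathway
sets with the one-sided Fisher (hypergeometric upper-tail) test
(`pathway_enrich()`). Set members absent from the stratum's expression
universe are removed first. Pathways overlapping the class list by fewer
than `min_overlap = 5` genes are discarded *untested* and excluded from
the Bonferroni family — an untested hypothesis should not pay, nor charge,
multiplicity. "Overlap" is read against the tested gene list, not the
universe, because the discard exists to avoid unstable tiny-overlap tests.
Significance is Bonferroni-adjusted p below `enrich_alpha = 0.01` within
the tissue-by-class family. A pathway-class pair survives only if
significant in at least `min_contexts = 2` contexts (tissues of either
species), matched per class panel: a linear-up hit in one tissue does not
rescue a linear-down hit elsewhere. Circle summaries then count each
retained pathway's age-related genes per tissue and contrast age, binned
small (0–5), medium (6–15), large (>15), with the geometric-mean fold
change versus the reference age and a display saturation bound of 4-fold.

### Ortholog direction concordance

Given trajectory classes for two species and a first-candidate ortholog
map, `ortholog_concordance()` counts, per tissue and direction and in both
mapping orientations (the map need not be a bijection, so the orientations
differ): n mapped age-related query genes of the direction, k of them with
same-direction age-related orthologs, K same-direction targets among all N
mapped query genes. The probability of k or more concordant pairs is the
upper-tail hypergeometric sum, evaluated with `lchoose` log-gamma
arithmetic because real-data values reach 1e-15 where naive factorials
overflow. Age-related genes are pooled over linear and logistic classes by
direction — the concordance question is about direction, not shape — and no
multiplicity correction is applied across tissues or directions: the raw
probabilities are the report. All N mapped genes count in the denominator
whether or not they are age-related.

### Transcription-factor association

Interactions (TF, target) are kept when the TF is on the supplied
whitelist (in real use: DNA-binding transcription-factor GO terms) and both
genes are age-related in at least one tissue (`filter_interactions()`).
Surviving interactions are ranked by Spearman correlation across *all*
samples of the species (`rank_by_spearman()`); pooling across tissues is
the default because regulator-target coupling is a species-level claim, but
the stratification is the caller's choice since the functions compose. Ties
in rho are broken lexicographically so the ranking is deterministic.

For each enriched level-2 pathway system (pathways map to systems through a
supplied table), the "relevant" genes are those carrying the retained class
label in at least `tf_min_tissues = 2` tissues and annotated to the system;
a TF's set is its interactions with relevant targets, dropped below
`min_tf_targets = 5` (`build_target_sets()`). Each set is scored on the
ranked list with a pre-ranked GSEA running sum — hits advance by
`|rho| / sum(|rho|)` over the set, misses retreat by `1/(L - m)` — whose
maximal deviation is the enrichment score (`preranked_gsea()`). The p-value
is a seeded Monte-Carlo probability of an `|ES|` at least as extreme among
`n_perm = 10000` uniformly drawn same-size sets (gene-set permutation), and
Benjamini-Hochberg adjustment runs across all TF-system rows at
`tf_alpha = 0.05`. The weighting exponent is 1 and the adjustment is BH —
the defaults of the standard pre-ranked GSEA tool; the adaptive multilevel
permutation scheme of that tool is out of scope, so the Monte-Carlo p has
resolution `1/(n_perm + 1)`.

## The synthetic-data generator

`sim_design()` / `sim_truth()` / `sim_counts()` emulate the study design
this pipeline targets: ages 6, 12, 18, 21, 24, 27 months (a rat mode adds
9), 8 samples per group by default in `sim_study()` (within the 8-12
animals per group typical of such designs; `sim_design()` alone defaults
to 10), gene-wise negative-binomial counts with log-normal dispersion
(median 0.05, a realistic bulk RNA-seq value), log-normal library sizes
(median 2e7), and planted null/linear/logistic log2-CPM trajectories. The
planted curves use the *same* `logistic4()` implementation as the fitter,
so truth and model agree exactly on a grid by construction — recovery
failures are then attributable to noise and selection, not to formula
drift. Linear genes default to ±0.05 log2-CPM per month (about 1 log2 unit
across the design, near the DE fold gate — a deliberately moderate effect);
logistic genes move 2 log2 units between plateaus with inflections drawn
inside the age range.

`sim_gene_sets()` plants over-represented pathway sets (75% of members
from one class/direction by default), `sim_ortholog_map()` plants a 1:1
partially concordant cross-species map (age-related query genes paired
with same-direction partners with the stated probability; age-related
genes are paired first so the partner pools are not consumed by the
uniform background), and `sim_tf_network()` plants regulators whose
trajectories are noisy copies of their targets' mean trajectory.
`sim_study()` wires all of it into a two-species, two-tissue study whose
tissues share each species' truth table, so planted signals legitimately
recur across tissues and exercise the cross-tissue filter and the
shared-gene reports.

What the generator does **not** emulate: batch effects, sex-specific
biology, composition biases between samples, read-level error, correlated
gene-gene noise, and the long-tailed set-size distribution of real pathway
databases. Passing tests on this generator therefore demonstrate the
*statistical machinery* — gates, fits, selection rules, tail probabilities,
permutation calibration — not robustness to the full messiness of real
RNA-seq; on real data the DE engine's assumptions (equal group variances
on log2-CPM, independence across genes) are approximations.

## Numerical choices

* RSS is floored at `rss_floor = 1e-12` before the BIC log so perfect fits
  stay finite; only pathological noise-free fixtures hit the floor.
* The logistic fit profiles the plateaus: for fixed `(c, b)` the curve is
  linear in `(A, D)`, solved by least squares over a deterministic start
  grid (`c` at each observed age, `b` in ±{0.2, 1, 5} — shallow, moderate
  and step-like), then polished with bounded L-BFGS-B, keeping the polished
  solution only when it lowers the RSS. The grid is part of the method's
  contract: the final RSS can never exceed the exhaustive grid optimum, and
  the suite asserts exactly that. There is no randomness and hence no seed
  in the fit.
* A logistic fit that fails on every start leaves the gene to the
  null/linear comparison and is flagged, rather than aborting the stratum.
* The concordance tail sum runs from its largest term in log space, which
  holds six significant digits at p ~ 1e-15.
* Monte-Carlo GSEA p-values use the `(1 + hits) / (1 + n_perm)` estimator,
  which is never exactly zero and is exactly discrete-uniform under the
  null.
* `squeeze_var()` inverts the trigamma function by Newton iteration; when
  the observed log-variance spread is below its sampling floor the prior
  degrees of freedom are infinite and all gene variances collapse to the
  common value — the correct limit, also asserted in tests.

## Problem sizes

The shipped tests and the acceptance script run, by choice, at desk scale:
the parameter-recovery stratum uses 5000 genes (100 planted linear-up at
slope 0.05, dispersion 0.05, 10 samples per group), null calibration uses
200 replicates of 200-gene two-group studies, the uniformity checks use
400-500 replicates, and the end-to-end study uses 1200 genes per species,
two tissues and 8 samples per group. These sizes make every claim
recomputable in minutes on one CPU while keeping the planted effects at
realistic magnitudes.

## Known limitations

* The DE engine is a per-contrast two-sample comparison with variance
  moderation, not a full design-matrix linear model; covariates beyond the
  stratification (species, sex, tissue) are not supported.
* Inflection-age estimates carry no uncertainty intervals; staging near the
  12- and 21-month boundaries is sensitive to noise at modest n.
* The Monte-Carlo GSEA p cannot resolve below `1/(n_perm + 1)`.
* Gene identifiers are opaque case-sensitive strings; no symbol or
  ortholog inference is performed — the ortholog map is an input.
* Single-process execution; the strata loop is embarrassingly parallel but
  deliberately sequential for determinism and simplicity.
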