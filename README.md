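# agesig

Multi-tissue, multi-time-point aging gene-expression signatures from bulk
RNA-seq time courses.

## The problem

Rodent aging studies profile several skeletal muscles (and other tissues) at
many ages across the lifespan — e.g. 6, 9, 12, 18, 21, 24 and 27 months —
and ask which genes change with age, *how* they change (steadily, or
switch-like at a particular age), which pathways those genes converge on,
whether the changes are conserved between species, and which transcription
factors might drive them. `agesig` implements that full analysis as a
tested, reusable R pipeline, together with a synthetic-data generator with
planted ground truth so every stage is verifiable without external data.

## The method

For each stratum (species × sex × tissue):

1. **Normalisation & DE gating.** Counts are normalised to
   log2 CPM = log2((count + 0.5) / (libsize + 1) × 10⁶). A gene is
   differentially expressed if, at any age versus the reference age,
   |log2 FC| > log2(1.5) and the Bonferroni-adjusted p (two-sample test
   with empirical-Bayes variance moderation) is below 0.05.
2. **Trajectory classification.** Each DE gene's log2 CPM over age t is fit
   with three models: a constant, a line, and the 4-parameter logistic
   f(t) = A + (D − A) / (1 + exp(−b (t − c))), D ≥ A. With
   BIC = n ln(RSS/n) + k ln n (k = 1, 2, 4), a gene is *age-related* when
   min(BIC_lin, BIC_logis) < BIC_null − 6, and *linear* unless
   BIC_logis < BIC_lin − 2. Logistic genes are staged by the inflection c:
   early (< 12 mo), mid (12–21 mo), late (> 21 mo); direction comes from
   the slope or the sign of the Hill coefficient b.
3. **Pathway enrichment.** Each class list is tested against pathway sets
   with the one-sided Fisher (hypergeometric) test; overlaps below 5 genes
   are discarded untested; Bonferroni-adjusted p < 0.01 is significant, and
   only pathways enriched in ≥ 2 tissues (of the same or different species)
   are retained. Circle summaries report genes-per-pathway bins and mean
   fold changes per age.
4. **Ortholog concordance.** With a first-candidate ortholog map, the
   probability that k or more of n mapped age-related query genes have
   same-direction age-related orthologs, among K same-direction targets out
   of N mapped genes, is the upper-tail hypergeometric
   p = Σᵢ₌ₖⁿ C(K,i) C(N−K,n−i) / C(N,n), computed in log-gamma arithmetic.
5. **TF association.** Regulator–target interactions (GO-whitelisted TFs,
   both genes age-related) are ranked by Spearman correlation across all
   samples of the species; each TF's interactions with the relevant genes
   of an enriched level-2 pathway system (≥ 5 targets) are scored with a
   pre-ranked GSEA running sum and a seeded permutation p, BH-adjusted at
   0.05.

## Worked example

```r
library(agesig)

study <- sim_study(seed = 42)          # two species, two tissues, planted truth
res   <- run_pipeline(study, seed = 42)
glance(res)
#> # A tibble: 1 × 6
#>   n_strata n_de_rows n_age_related n_retained_pathways n_concordance_tests
#>      <int>     <int>         <int>               <int>               <int>
#> 1        4     26576           660                   3                   8
#> # i 1 more variable: n_tf_significant <int>
```

Four strata (2 species × 2 tissues) were processed; 660 gene × stratum
records are age-related, three planted pathways survive the two-tissue
filter, and eight concordance tests (2 tissues × 2 directions × 2 mapping
orientations) were run. The worked concordance example —

```r
concordance_test(82, 20, 369, 14838)
#> [1] 7.462403e-15
```

— is the probability that 20 or more of 82 mapped upregulated genes have
same-direction orthologs when 369 of the 14838 mapped genes qualify: far
too many to be chance, i.e. strong cross-species conservation of direction.
The BIC decision on a gene with `null_bic = 100, linear_bic = 95.9,
logistic_bic = 93.9`:

```r
select_model(100, 95.9, 93.9)
#> [1] "linear"
```

the logistic beats the null by more than 6 (age-related), but not the
linear by more than 2, so the simpler line wins.

## Package layout

- `R/sim.R` — synthetic-data generator (designs, truth tables, NB counts,
  planted gene sets, ortholog maps, regulator networks)
- `R/io.R` — TSV/MTX/GMT/pair-table readers, result writer, run manifest
- `R/de.R` — log2-CPM, moderated contrasts, DE gates
- `R/trajectory.R` — model fits, BIC selection, staging, classification
- `R/enrichment.R`, `R/concordance.R`, `R/tf.R` — downstream stages
- `R/pipeline.R` — orchestration, config files, reporting
- `vignettes/aging-signatures.Rmd` — the methods vignette
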