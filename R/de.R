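#' Normalise counts to log2 counts-per-million
#'
#' Entry for gene g in sample s is
#' `log2((count + prior) / (libsize_s + 2 * prior) * 1e6)`, the standard
#' prior-damped log-CPM. The prior keeps zero counts finite; library size is
#' the raw column sum.
#'
#' @param counts A `count_matrix` from [as_count_matrix()], or a wide tibble
#'   whose first column is `gene_id`.
#' @param prior Pseudo-count added to every count (default 0.5).
#' @return A wide tibble of log2-CPM values (`gene_id` + samples) with the
#'   prior and library sizes stored as attributes.
#' @examples
#' cm <- tibble::tibble(gene_id = c("a", "b"), s1 = c(100L, 0L), s2 = c(5L, 5L))
#' log2_cpm(cm)
#' @export
log2_cpm <- function(counts, prior = 0.5) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  lib <- colSums(m)
  if (any(lib <= 0)) {
    abort("zero library size", class = "agesig_input_error")
  }
  lc <- log2(sweep(m + prior, 2, lib + 2 * prior, `/`) * 1e6)
  out <- as_tibble(lc)
  out <- dplyr::bind_cols(tibble(gene_id = counts$gene_id), out)
  attr(out, "prior") <- prior
  attr(out, "lib_sizes") <- lib
  out
}

# Internal: wide tibble -> matrix with gene_id rownames.
expr_matrix <- function(expr) {
  m <- as.matrix(expr[setdiff(names(expr), "gene_id")])
  rownames(m) <- expr$gene_id
  m
}

# Newton inversion of the trigamma function, used by the empirical-Bayes
# variance moderation (method of moments on log sample variances).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Empirical-Bayes squeeze of gene-wise variances
#'
#' Shrinks each gene's sample variance toward a common prior:
#' `s2_tilde = (d0 * s0^2 + df * s2) / (d0 + df)`. The prior degrees of
#' freedom `d0` and prior variance `s0^2` are estimated by method of
#' moments on `log(s2)`, matching the scaled-F marginal of gene variances
#' (the limma-style hierarchical model).
#'
#' @param s2 Gene-wise sample variances.
#' @param df Residual degrees of freedom of each `s2` (scalar).
#' @return List with `var_post`, `df_prior` (`d0`, may be `Inf`), and
#'   `var_prior` (`s0^2`).
#' @export
squeeze_var <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) {
    return(list(var_post = s2, df_prior = 0, var_prior = NA_real_))
  }
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(z) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s0 <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  var_post <- if (is.infinite(d0)) {
    rep(s0, length(s2))
  } else {
    (d0 * s0 + df * s2) / (d0 + df)
  }
  list(var_post = var_post, df_prior = d0, var_prior = s0)
}

#' Test one age against the reference age
#'
#' Per gene: `log2_fc = mean(age) - mean(ref)`, a two-sided test on the mean
#' difference using the pooled two-group variance, optionally moderated by
#' [squeeze_var()] (default on). The moderated statistic uses
#' `df + df_prior` degrees of freedom.
#'
#' @param expr A [log2_cpm()] tibble.
#' @param metadata Per-sample tibble with `sample_id` and `age_months`.
#' @param age Contrast age (months).
#' @param ref_age Reference age (months).
#' @param moderation Apply empirical-Bayes variance moderation?
#' @return Tibble: `gene_id`, `contrast_age`, `log2_fc`, `stat`, `df`, `p`.
#' @export
fit_contrast <- function(expr, metadata, age, ref_age, moderation = TRUE) {
  m <- expr_matrix(expr)
  s1 <- metadata$sample_id[metadata$age_months == age]
  s0 <- metadata$sample_id[metadata$age_months == ref_age]
  s1 <- intersect(s1, colnames(m))
  s0 <- intersect(s0, colnames(m))
  if (length(s1) < 2 || length(s0) < 2) {
    abort(sprintf("age groups %s and %s need >= 2 samples each", age, ref_age),
          class = "agesig_input_error")
  }
  x1 <- m[, s1, drop = FALSE]
  x0 <- m[, s0, drop = FALSE]
  n1 <- length(s1); n0 <- length(s0)
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  ss1 <- rowSums((x1 - m1)^2)
  ss0 <- rowSums((x0 - m0)^2)
  df <- n1 + n0 - 2
  s2 <- (ss1 + ss0) / df
  df_total <- df
  if (moderation) {
    sq <- squeeze_var(s2, df)
    s2 <- sq$var_post
    df_total <- df + sq$df_prior
  }
  se <- sqrt(s2 * (1 / n1 + 1 / n0))
  fc <- m1 - m0
  stat <- ifelse(se > 0, fc / se, ifelse(fc == 0, 0, sign(fc) * Inf))
  p <- 2 * pt(abs(stat), df = df_total, lower.tail = FALSE)
  tibble(
    gene_id = rownames(m), contrast_age = age,
    log2_fc = unname(fc), stat = unname(stat), df = unname(df_total),
    p = unname(p)
  )
}

#' Test every age against the reference age
#'
#' @param expr A [log2_cpm()] tibble.
#' @param metadata Per-sample metadata.
#' @param ref_age Reference age; defaults to the youngest age present.
#' @param moderation Passed to [fit_contrast()].
#' @return Row-bound [fit_contrast()] tibbles, one block per non-reference age.
#' @export
fit_all_contrasts <- function(expr, metadata, ref_age = NULL, moderation = TRUE) {
  metadata <- filter(metadata, .data$sample_id %in% names(expr))
  ages <- sort(unique(metadata$age_months))
  if (is.null(ref_age)) ref_age <- min(ages)
  bind_rows(lapply(setdiff(ages, ref_age), function(a) {
    fit_contrast(expr, metadata, age = a, ref_age = ref_age,
                 moderation = moderation)
  }))
}

#' Apply the fold-change and Bonferroni gates
#'
#' A gene is differentially expressed at a contrast iff
#' `|log2_fc| > log2(fc_threshold)` and the Bonferroni-adjusted p is below
#' `alpha`; the DE universe is the union over contrasts ("at any age").
#' Bonferroni adjusts across genes within each contrast by default; set
#' `family = "global"` to adjust across genes x contrasts.
#'
#' @param de_rows Output of [fit_all_contrasts()].
#' @param fc_threshold Fold-change gate on the natural scale (default 1.5).
#' @param alpha Adjusted-p gate (default 0.05).
#' @param family `"per_contrast"` or `"global"` Bonferroni family.
#' @return `de_rows` plus `p_adj` and `is_de`, with the DE universe in
#'   `attr(, "de_universe")` and the family size in `attr(, "family_size")`.
#' @export
call_de <- function(de_rows, fc_threshold = 1.5, alpha = 0.05,
                    family = c("per_contrast", "global")) {
  family <- match.arg(family)
  out <- de_rows %>%
    group_by(.data$contrast_age) %>%
    mutate(.m = dplyr::n()) %>%
    ungroup()
  fam <- if (family == "global") nrow(out) else out$.m
  out <- out %>%
    mutate(
      p_adj = pmin(1, .data$p * fam),
      is_de = abs(.data$log2_fc) > log2(fc_threshold) & .data$p_adj < alpha
    ) %>%
    select(-".m")
  attr(out, "de_universe") <- sort(unique(out$gene_id[out$is_de]))
  attr(out, "family_size") <- if (family == "global") nrow(out) else
    unique(fam)
  out
}

#' Genes differentially expressed at one or more ages
#'
#' @param de_called Output of [call_de()].
#' @return Character vector of gene ids.
#' @export
de_universe <- function(de_called) {
  sort(unique(de_called$gene_id[de_called$is_de]))
}
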