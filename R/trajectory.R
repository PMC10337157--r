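#' Fit null, linear and 4-parameter logistic trajectory models to one gene
#'
#' Fits three nested descriptions of log2-CPM versus age: a constant (grand
#' mean), an ordinary least-squares line, and the four-parameter logistic
#' [logistic4()] with the inflection constrained to the observed age range.
#' The logistic fit profiles the two plateaus (linear in the curve for fixed
#' `c`, `b`) over a deterministic multi-start grid — `c` at each observed
#' age, `b` in `{-5, -1, -0.2, 0.2, 1, 5}` — then polishes the best start
#' with bounded quasi-Newton iterations, keeping the polished solution only
#' if it lowers the RSS. Plateaus are normalised to `A <= D` (swapping and
#' flipping the sign of `b` leaves the curve unchanged), so `sign(b)` alone
#' encodes direction. BIC is `n * log(RSS / n) + k * log(n)` with
#' `k = 1, 2, 4`; the RSS is floored at `rss_floor` to keep BIC finite on
#' perfect fits.
#'
#' @param y Log2-CPM values, one per sample.
#' @param t Ages in months, same length as `y`; needs >= 3 distinct values.
#' @param b_grid Magnitudes of the Hill-coefficient starts (both signs used).
#' @param rss_floor Lower bound applied to each RSS before the log.
#' @param polish Run the quasi-Newton refinement after the grid search?
#' @return One-row tibble: `n`, per-model RSS and BIC, `linear_slope`,
#'   `linear_intercept`, logistic `A`, `D`, `c`, `b`, and `logistic_ok`.
#' @examples
#' fit_trajectory(c(1, 2, 2), c(1, 2, 3))
#' @export
fit_trajectory <- function(y, t, b_grid = c(0.2, 1, 5), rss_floor = 1e-12,
                           polish = TRUE) {
  stopifnot(length(y) == length(t))
  keep <- is.finite(y) & is.finite(t)
  y <- y[keep]; t <- t[keep]
  n <- length(y)
  ages <- sort(unique(t))
  if (length(ages) < 3) {
    abort("need >= 3 distinct ages to fit trajectories",
          class = "agesig_input_error")
  }

  # null model: grand mean
  null_rss <- sum((y - mean(y))^2)

  # linear model: closed-form OLS
  tc <- t - mean(t)
  slope <- sum(tc * y) / sum(tc^2)
  intercept <- mean(y) - slope * mean(t)
  linear_rss <- sum((y - intercept - slope * t)^2)

  # logistic model: profiled (A, D) over a (c, b) start grid
  best <- list(rss = Inf, par = NULL)
  for (cc in ages) {
    for (b in c(-rev(b_grid), b_grid)) {
      s <- 1 / (1 + exp(-b * (t - cc)))
      X <- cbind(1 - s, s)
      fit <- tryCatch(.lm.fit(X, y), error = function(e) NULL)
      if (is.null(fit) || fit$rank < 2) next
      rss <- sum(fit$residuals^2)
      if (rss < best$rss) {
        best <- list(rss = rss,
                     par = c(A = fit$coefficients[1], D = fit$coefficients[2],
                             c = cc, b = b))
      }
    }
  }
  logistic_ok <- is.finite(best$rss)
  if (logistic_ok && polish) {
    obj <- function(p) {
      r <- y - logistic4(t, p[1], p[2], p[3], p[4])
      sum(r * r)
    }
    pol <- tryCatch(
      optim(best$par, obj, method = "L-BFGS-B",
            lower = c(-Inf, -Inf, min(t), -50),
            upper = c(Inf, Inf, max(t), 50),
            control = list(maxit = 200)),
      error = function(e) NULL
    )
    if (!is.null(pol) && is.finite(pol$value) && pol$value < best$rss) {
      best <- list(rss = pol$value, par = pol$par)
    }
  }
  if (logistic_ok && best$par[1] > best$par[2]) {
    best$par <- c(A = unname(best$par[2]), D = unname(best$par[1]),
                  c = unname(best$par[3]), b = -unname(best$par[4]))
  }

  bic <- function(rss, k) n * log(max(rss, rss_floor) / n) + k * log(n)
  tibble(
    n = n,
    null_rss = null_rss, null_bic = bic(null_rss, 1),
    linear_rss = linear_rss, linear_bic = bic(linear_rss, 2),
    linear_slope = slope, linear_intercept = intercept,
    logistic_rss = if (logistic_ok) best$rss else NA_real_,
    logistic_bic = if (logistic_ok) bic(best$rss, 4) else NA_real_,
    logistic_A = if (logistic_ok) unname(best$par[1]) else NA_real_,
    logistic_D = if (logistic_ok) unname(best$par[2]) else NA_real_,
    logistic_c = if (logistic_ok) unname(best$par[3]) else NA_real_,
    logistic_b = if (logistic_ok) unname(best$par[4]) else NA_real_,
    logistic_ok = logistic_ok
  )
}

#' Select a trajectory model from the three BICs
#'
#' The gene stays `"null"` unless the better of the linear and logistic BICs
#' undercuts the null BIC by more than `evidence_cutoff`. Among age-related
#' genes the simpler line wins unless the logistic BIC undercuts the linear
#' BIC by more than `linear_priority`.
#'
#' @param null_bic,linear_bic,logistic_bic BIC vectors (logistic may be `NA`
#'   when that fit was unavailable).
#' @param evidence_cutoff Required BIC gap to the null model (default 6).
#' @param linear_priority BIC gap the logistic must win by (default 2).
#' @return Character vector in `{"null", "linear", "logistic"}`.
#' @examples
#' select_model(100, 95.9, 93.9)  # "linear": logistic beats null, not linear
#' @export
select_model <- function(null_bic, linear_bic, logistic_bic,
                         evidence_cutoff = 6, linear_priority = 2) {
  logistic_bic <- ifelse(is.na(logistic_bic), Inf, logistic_bic)
  best_alt <- pmin(linear_bic, logistic_bic)
  ifelse(
    best_alt >= null_bic - evidence_cutoff, "null",
    ifelse(logistic_bic < linear_bic - linear_priority, "logistic", "linear")
  )
}

#' Stage a logistic gene by its inflection age
#'
#' Early before 12 months, mid between 12 and 21 months (inclusive at both
#' bounds), late after 21 months.
#'
#' @param c Inflection ages in months.
#' @param bounds Stage boundaries (months), default `c(12, 21)`.
#' @return Character vector in `{"early", "mid", "late"}`.
#' @examples
#' stage_logistic(c(10, 21, 25))
#' @export
stage_logistic <- function(c, bounds = c(12, 21)) {
  ifelse(c < bounds[1], "early", ifelse(c <= bounds[2], "mid", "late"))
}

#' Classify every differentially expressed gene's trajectory
#'
#' Fits the three models to each DE gene's log2-CPM over age and emits the
#' nine-way label: `not_age_related`, `linear_up/down`, or
#' `early/mid/late_up/down` (stage from the logistic inflection, direction
#' from the linear slope or the Hill-coefficient sign). Genes outside the DE
#' universe are labelled `not_age_related` without fitting.
#'
#' @param expr A [log2_cpm()] tibble.
#' @param metadata Per-sample metadata (`sample_id`, `age_months`).
#' @param de_genes Character vector: the DE universe.
#' @param evidence_cutoff,linear_priority Passed to [select_model()].
#' @param stage_bounds Passed to [stage_logistic()].
#' @param rss_floor Passed to [fit_trajectory()].
#' @return A `trajectory_result` list: `classes` (tibble `gene_id`, `label`),
#'   `fits` (one [fit_trajectory()] row per DE gene plus `model`), and
#'   `counts` (genes per label).
#' @export
classify_trajectories <- function(expr, metadata, de_genes,
                                  evidence_cutoff = 6, linear_priority = 2,
                                  stage_bounds = c(12, 21), rss_floor = 1e-12) {
  metadata <- filter(metadata, .data$sample_id %in% names(expr))
  m <- expr_matrix(expr)
  m <- m[, metadata$sample_id, drop = FALSE]
  ages <- metadata$age_months
  de_genes <- intersect(de_genes, rownames(m))

  fits <- NULL
  labels <- setNames(rep("not_age_related", nrow(m)), rownames(m))
  if (length(de_genes) > 0) {
    fits <- bind_rows(lapply(de_genes, function(g) {
      fit_trajectory(m[g, ], ages, rss_floor = rss_floor)
    }))
    fits <- dplyr::bind_cols(tibble(gene_id = de_genes), fits)
    fits$model <- select_model(fits$null_bic, fits$linear_bic,
                               fits$logistic_bic,
                               evidence_cutoff = evidence_cutoff,
                               linear_priority = linear_priority)
    lab <- dplyr::case_when(
      fits$model == "null" ~ "not_age_related",
      fits$model == "linear" & fits$linear_slope > 0 ~ "linear_up",
      fits$model == "linear" ~ "linear_down",
      fits$model == "logistic" ~ paste0(
        stage_logistic(fits$logistic_c, stage_bounds),
        ifelse(fits$logistic_b > 0, "_up", "_down")
      )
    )
    labels[fits$gene_id] <- lab
  }
  classes <- tibble(gene_id = names(labels), label = unname(labels))
  counts <- classes %>%
    filter(.data$label != "not_age_related") %>%
    count(.data$label, name = "n_genes")
  structure(
    list(classes = classes, fits = fits, counts = counts,
         params = list(evidence_cutoff = evidence_cutoff,
                       linear_priority = linear_priority,
                       stage_bounds = stage_bounds)),
    class = "trajectory_result"
  )
}

#' @export
print.trajectory_result <- function(x, ...) {
  n_age <- sum(x$classes$label != "not_age_related")
  cat("<trajectory_result> ", nrow(x$classes), " genes, ",
      n_age, " age-related\n", sep = "")
  if (n_age > 0) print(x$counts)
  invisible(x)
}

#' @method tidy trajectory_result
#' @export
tidy.trajectory_result <- function(x, ...) {
  out <- x$classes
  if (!is.null(x$fits)) {
    out <- left_join(out, select(x$fits, "gene_id", "model", "null_bic",
                                 "linear_bic", "logistic_bic", "linear_slope",
                                 "logistic_c", "logistic_b"),
                     by = "gene_id")
  }
  out
}

#' @method glance trajectory_result
#' @export
glance.trajectory_result <- function(x, ...) {
  tibble(
    n_genes = nrow(x$classes),
    n_age_related = sum(x$classes$label != "not_age_related"),
    n_linear = sum(grepl("^linear", x$classes$label)),
    n_logistic = sum(grepl("^(early|mid|late)", x$classes$label)),
    evidence_cutoff = x$params$evidence_cutoff,
    linear_priority = x$params$linear_priority
  )
}
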