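test_that("closed-form OLS and BIC arithmetic match the hand computation", {
  fit <- fit_trajectory(c(1, 2, 2), c(1, 2, 3))
  expect_equal(fit$null_rss, 2 / 3, tolerance = 1e-12)
  expect_equal(fit$linear_rss, 1 / 6, tolerance = 1e-12)
  expect_equal(fit$null_bic, 3 * log(2 / 9) + log(3), tolerance = 1e-10)
  expect_equal(fit$linear_bic, 3 * log(1 / 18) + 2 * log(3), tolerance = 1e-10)
  expect_equal(fit$linear_slope, 0.5, tolerance = 1e-12)
  expect_error(fit_trajectory(c(1, 2, 3, 4), c(1, 1, 2, 2)),
               class = "agesig_input_error")
})

test_that("the BIC decision rule reproduces its worked example and bounds", {
  expect_equal(select_model(100, 95.9, 93.9), "linear")
  expect_equal(select_model(100, 95.0, 92.0), "logistic")
  expect_equal(select_model(100, 95.0, 96.0), "null")
  expect_equal(select_model(100, 93.9, NA), "linear")
  expect_equal(select_model(100, 99, 99.5), "null")
  # vectorised
  expect_equal(select_model(c(100, 100), c(95.9, 80), c(93.9, 70)),
               c("linear", "logistic"))
})

test_that("logistic staging uses the 12/21-month boundaries inclusively", {
  expect_equal(stage_logistic(10), "early")
  expect_equal(stage_logistic(12), "mid")
  expect_equal(stage_logistic(21), "mid")
  expect_equal(stage_logistic(25), "late")
  expect_equal(stage_logistic(11.999), "early")
})

ages6 <- rep(c(6, 12, 18, 21, 24, 27), each = 3)

test_that("noise-free logistic data recover the planted inflection", {
  y <- logistic4(ages6, A = 5, D = 7, c = 20, b = 1)
  set.seed(1)
  y <- y + rnorm(length(y), 0, 0.02)
  fit <- fit_trajectory(y, ages6)
  expect_true(fit$logistic_ok)
  expect_lt(abs(fit$logistic_c - 20), 0.5)
  expect_gt(fit$logistic_b, 0)
  expect_lt(fit$logistic_bic, fit$null_bic - 6)
  expect_lt(fit$logistic_bic, fit$linear_bic - 2)
})

test_that("near-linear data prefer the line and the gap grows as noise shrinks", {
  gaps <- vapply(c(0.3, 0.1, 0.02), function(eps) {
    set.seed(4)
    y <- 2 + 0.1 * ages6 + rnorm(length(ages6), 0, eps)
    fit <- fit_trajectory(y, ages6)
    fit$null_bic - fit$linear_bic
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
  expect_gt(gaps[3], 6)
})

test_that("trajectory labels are antisymmetric under sign flip of the data", {
  set.seed(8)
  y <- logistic4(ages6, 4, 6, 23, 2) + rnorm(length(ages6), 0, 0.1)
  up <- fit_trajectory(y, ages6)
  dn <- fit_trajectory(-y, ages6)
  expect_equal(up$null_bic, dn$null_bic, tolerance = 1e-8)
  expect_equal(up$linear_bic, dn$linear_bic, tolerance = 1e-8)
  expect_equal(up$logistic_bic, dn$logistic_bic, tolerance = 1e-6)
  expect_equal(up$logistic_b, -dn$logistic_b, tolerance = 1e-4)
  expect_equal(sign(up$linear_slope), -sign(dn$linear_slope))

  # intercept shifts change no BIC difference
  sh <- fit_trajectory(y + 100, ages6)
  expect_equal(up$null_bic - up$linear_bic, sh$null_bic - sh$linear_bic,
               tolerance = 1e-6)
  expect_equal(up$null_bic - up$logistic_bic, sh$null_bic - sh$logistic_bic,
               tolerance = 1e-4)
})

test_that("the optimizer never loses to an exhaustive grid search", {
  set.seed(15)
  for (rep in 1:12) {
    tt <- rep(c(6, 12, 18, 27), each = 3)
    y <- rnorm(12, mean = 5, sd = 1)
    fit <- fit_trajectory(y, tt)
    # independent exhaustive search over the frozen start grid
    grid_best <- Inf
    for (cc in unique(tt)) {
      for (b in c(-5, -1, -0.2, 0.2, 1, 5)) {
        s <- 1 / (1 + exp(-b * (tt - cc)))
        rss <- tryCatch(sum(stats::lm.fit(cbind(1 - s, s), y)$residuals^2),
                        error = function(e) Inf)
        grid_best <- min(grid_best, rss)
      }
    }
    expect_lte(fit$logistic_rss, grid_best + 1e-6)
  }
})

test_that("classification handles empty DE universes and planted strata", {
  d <- sim_design(n_genes = 60, n_per_group = 6,
                  fractions = c(0.5, 0.3, 0.2), slope = 0.08)
  tr <- sim_truth(d, seed = 44)
  s <- sim_counts(tr, d, seed = 45)
  lc <- log2_cpm(s$counts)

  res0 <- classify_trajectories(lc, s$metadata, character(0))
  expect_true(all(res0$classes$label == "not_age_related"))
  expect_equal(nrow(res0$counts), 0)

  de <- call_de(fit_all_contrasts(lc, s$metadata))
  res <- classify_trajectories(lc, s$metadata, de_universe(de))
  expect_equal(nrow(res$classes), 60)
  expect_setequal(unique(res$classes$label[res$classes$label != "not_age_related"]),
                  intersect(unique(res$classes$label),
                            c("linear_up", "linear_down", "early_up", "early_down",
                              "mid_up", "mid_down", "late_up", "late_down")))
  # tidiers
  td <- tidy(res)
  expect_true(all(c("gene_id", "label", "model") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_genes, 60)
  expect_equal(gl$n_age_related, sum(res$classes$label != "not_age_related"))
})

test_that("raising the evidence cutoff only removes age-related genes", {
  d <- sim_design(n_genes = 80, n_per_group = 6,
                  fractions = c(0.4, 0.3, 0.3), slope = 0.07)
  tr <- sim_truth(d, seed = 51)
  s <- sim_counts(tr, d, seed = 52)
  lc <- log2_cpm(s$counts)
  de <- de_universe(call_de(fit_all_contrasts(lc, s$metadata)))
  counts <- vapply(c(2, 6, 10, 20, Inf), function(cut) {
    r <- classify_trajectories(lc, s$metadata, de, evidence_cutoff = cut)
    sum(r$classes$label != "not_age_related")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[5], 0)
})
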