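test_that("truth tables honour fractions, determinism and field invariants", {
  d <- sim_design(n_genes = 100, fractions = c(1, 0, 0))
  tr <- sim_truth(d, seed = 1)
  expect_equal(nrow(tr), 100)
  expect_true(all(tr$true_class == "null"))
  expect_true(all(tr$direction == "none"))

  d2 <- sim_design(n_genes = 1000, fractions = c(0.8, 0.1, 0.1))
  tr2 <- sim_truth(d2, seed = 1)
  expect_equal(unname(table(tr2$true_class)[c("null", "linear", "logistic")]),
               c(800L, 100L, 100L), ignore_attr = TRUE)
  expect_identical(tr2, sim_truth(d2, seed = 1))

  # direction = none iff null; linear slope sign matches direction;
  # logistic inflection inside the age range with nonzero steepness
  expect_identical(tr2$true_class == "null", tr2$direction == "none")
  lin <- tr2[tr2$true_class == "linear", ]
  expect_true(all(sign(lin$slope) == ifelse(lin$direction == "up", 1, -1)))
  lg <- tr2[tr2$true_class == "logistic", ]
  expect_true(all(lg$inflection_c > 6 & lg$inflection_c < 27))
  expect_true(all(lg$hill_b != 0))

  expect_error(sim_design(fractions = c(0.5, 0.2, 0.1)),
               class = "agesig_config_error")
})

test_that("planted trajectories follow the shared model formulas exactly", {
  d <- sim_design(n_genes = 60, fractions = c(0.2, 0.4, 0.4), slope = 0.05)
  tr <- sim_truth(d, seed = 3)
  tt <- seq(6, 27, by = 1.5)
  mu <- truth_trajectory(tr, tt, ref_age = 6)
  for (i in which(tr$true_class == "linear")[1:5]) {
    expect_equal(mu[i, ], tr$baseline_log2cpm[i] + tr$slope[i] * (tt - 6))
  }
  for (i in which(tr$true_class == "logistic")[1:5]) {
    A <- if (tr$hill_b[i] >= 0) tr$baseline_log2cpm[i] else
      tr$baseline_log2cpm[i] - tr$amplitude[i]
    expect_equal(mu[i, ], logistic4(tt, A, A + tr$amplitude[i],
                                    tr$inflection_c[i], tr$hill_b[i]))
  }
  # a 0.05 log2/month slope accumulates 1.05 log2 between 6 and 27 months
  i <- which(tr$true_class == "linear" & tr$direction == "up")[1]
  expect_equal(unname(mu[i, ncol(mu)] - mu[i, 1]), 0.05 * 21)
})

test_that("simulated counts are reproducible and converge to the planted mean", {
  d <- sim_design(n_genes = 30, n_per_group = 4, fractions = c(0.5, 0.25, 0.25))
  tr <- sim_truth(d, seed = 2)
  a <- sim_counts(tr, d, seed = 9)
  b <- sim_counts(tr, d, seed = 9)
  expect_identical(a, b)
  expect_true(all(as.matrix(a$counts[-1]) >= 0))
  expect_equal(a$metadata$age_months, rep(d$ages, each = 4))

  # near-zero dispersion, many samples: empirical log2-CPM ~ planted mean
  d0 <- sim_design(n_genes = 20, n_per_group = 40,
                   fractions = c(0.5, 0.5, 0), slope = 0.05,
                   dispersion_meanlog = log(1e-5), dispersion_sdlog = 0)
  tr0 <- sim_truth(d0, seed = 4)
  s0 <- sim_counts(tr0, d0, seed = 5)
  lc <- log2_cpm(s0$counts, prior = 0.5)
  m <- as.matrix(lc[-1])
  mu <- truth_trajectory(tr0, s0$metadata$age_months, ref_age = 6)
  # with few simulated genes the realized library sums shift all log2-CPM
  # values by a common per-sample offset; the trajectory shape must match
  delta <- m - mu
  delta <- sweep(delta, 2, colMeans(delta))  # remove the common offset
  ages <- s0$metadata$age_months
  grp_err <- vapply(unique(ages), function(a) {
    rowMeans(delta[, ages == a, drop = FALSE])
  }, numeric(nrow(delta)))
  expect_lt(max(abs(grp_err)), 0.08)
})

test_that("null genes show no age trend at large n", {
  d <- sim_design(n_genes = 40, n_per_group = 50, fractions = c(1, 0, 0))
  tr <- sim_truth(d, seed = 11)
  s <- sim_counts(tr, d, seed = 12)
  lc <- log2_cpm(s$counts)
  m <- as.matrix(lc[-1])
  ages <- s$metadata$age_months
  pvals <- apply(m, 1, function(y) {
    summary(lm(y ~ ages))$coefficients[2, 4]
  })
  # two-sided trend test on the per-gene mean: most null genes flat
  expect_gt(median(pvals), 0.01)
  expect_lt(mean(pvals < 0.01), 0.15)
})

test_that("planted gene sets respect size bounds and enrichment settings", {
  d <- sim_design(n_genes = 500, fractions = c(0.6, 0.3, 0.1), p_up = 1)
  tr <- sim_truth(d, seed = 5)
  gs <- sim_gene_sets(tr, n_sets = 20, enriched_fraction = 0.2,
                      set_size = c(10, 30), purity = 0.75, seed = 6)
  expect_length(gs$sets, 20)
  sizes <- lengths(gs$sets)
  expect_true(all(sizes >= 10 & sizes <= 30))
  expect_equal(sum(gs$set_truth$enriched), 4)
  # enriched sets are dominated by the planted class
  pool <- tr$gene_id[tr$true_class == "linear" & tr$direction == "up"]
  frac_in <- vapply(gs$sets[gs$set_truth$enriched],
                    function(s) mean(s %in% pool), numeric(1))
  expect_true(all(frac_in >= 0.5))

  gs0 <- sim_gene_sets(tr, n_sets = 10, enriched_fraction = 0, seed = 6)
  expect_equal(sum(gs0$set_truth$enriched), 0)
  expect_error(sim_gene_sets(tr, n_sets = 2, set_size = c(600, 700)),
               class = "agesig_config_error")
})

test_that("ortholog maps plant concordance and stay one-to-one", {
  d <- sim_design(n_genes = 300, fractions = c(0.6, 0.2, 0.2))
  # a larger partner universe keeps same-direction pools from exhausting
  db <- sim_design(n_genes = 450, fractions = c(0.6, 0.2, 0.2))
  ta <- sim_truth(d, seed = 21, prefix = "a_")
  tb <- sim_truth(db, seed = 22, prefix = "b_")
  m <- sim_ortholog_map(ta, tb, concordance_prob = 1, coverage = 1, seed = 23)
  expect_equal(nrow(m), 300)
  expect_false(anyDuplicated(m$gene_a) > 0)
  expect_false(anyDuplicated(m$gene_b) > 0)
  dir_a <- setNames(ta$direction, ta$gene_id)
  dir_b <- setNames(tb$direction, tb$gene_id)
  age_a <- m$gene_a[dir_a[m$gene_a] != "none"]
  expect_true(all(dir_b[m$gene_b[match(age_a, m$gene_a)]] ==
                    dir_a[age_a]))
  expect_equal(nrow(sim_ortholog_map(ta, tb, coverage = 0, seed = 1)), 0)
  expect_identical(sim_ortholog_map(ta, tb, seed = 3),
                   sim_ortholog_map(ta, tb, seed = 3))
})

test_that("regulator networks plant correlated trajectories deterministically", {
  d <- sim_design(n_genes = 200, fractions = c(0.5, 0.5, 0), p_up = 1,
                  slope = 0.08)
  tr <- sim_truth(d, seed = 31)
  net <- sim_tf_network(tr, n_tfs = 6, targets_per_tf = 8,
                        correlated_fraction = 1, noise_sd = 0, seed = 32)
  expect_identical(net, sim_tf_network(tr, n_tfs = 6, targets_per_tf = 8,
                                       correlated_fraction = 1, noise_sd = 0,
                                       seed = 32))
  expect_equal(nrow(net$truth), 206)
  # noiseless correlated regulators share their targets' mean trajectory:
  # Spearman of the planted curves is exactly 1 for upward targets
  tt <- c(6, 12, 18, 21, 24, 27)
  mu <- truth_trajectory(net$truth, tt)
  for (f in net$tf_truth$tf[net$tf_truth$correlated][1:3]) {
    tg <- net$interactions$target[net$interactions$tf == f][1]
    expect_equal(cor(rank(mu[f, ]), rank(mu[tg, ])), 1)
  }
  # a regulator with fewer than 5 targets is representable
  net4 <- sim_tf_network(tr, n_tfs = 2, targets_per_tf = 4, seed = 33)
  expect_true(all(table(net4$interactions$tf) == 4))
})
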