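test_that("interaction filtering requires whitelist and both genes age-related", {
  inter <- tibble::tibble(
    tf = c("f1", "f1", "f2", "f3"),
    target = c("g1", "g2", "g1", "g1")
  )
  wl <- c("f1", "f2")
  age_rel <- c("f1", "g1")  # f2 not age-related, g2 not age-related
  out <- filter_interactions(inter, wl, age_rel)
  expect_equal(nrow(out), 1)
  expect_equal(out$tf, "f1")
  expect_equal(out$target, "g1")
  expect_warning(empty <- filter_interactions(inter, character(0), age_rel),
                 "whitelist")
  expect_equal(nrow(empty), 0)
})

test_that("Spearman ranking uses average ranks and a lexicographic tie rule", {
  expr <- tibble::tibble(
    gene_id = c("f", "g", "h", "const"),
    s1 = c(1, 3, 1, 5), s2 = c(2, 1, 2, 5), s3 = c(3, 2, 3, 5)
  )
  inter <- tibble::tibble(tf = c("f", "f"), target = c("g", "h"))
  r <- rank_by_spearman(expr, inter)
  expect_equal(r$rho[r$target == "g"], -0.5, tolerance = 1e-12)
  expect_equal(r$rho[r$target == "h"], 1, tolerance = 1e-12)
  expect_equal(r$target, c("h", "g"))  # sorted decreasing

  inter_c <- tibble::tibble(tf = "f", target = "const")
  expect_warning(rc <- rank_by_spearman(expr, inter_c), "constant")
  expect_equal(nrow(rc), 0)

  # deterministic tie-break on equal rho
  expr2 <- tibble::tibble(gene_id = c("f", "a", "b"),
                          s1 = c(1, 1, 1), s2 = c(2, 2, 2), s3 = c(3, 3, 3))
  r2 <- rank_by_spearman(expr2, tibble::tibble(tf = "f", target = c("b", "a")))
  expect_equal(r2$target, c("a", "b"))
})

test_that("the running-sum enrichment score matches the hand-walked oracle", {
  # 10-element list, set at ranks 1, 2, 5 with unit weights -> ES = 5/7
  expect_equal(agesig:::gsea_es(rep(1, 10), c(1, 2, 5)), 5 / 7,
               tolerance = 1e-12)
  # random weighted lists against the element-by-element walk
  set.seed(30)
  for (rep in 1:20) {
    L <- sample(8:20, 1)
    m <- sample(2:(L - 2), 1)
    w <- runif(L)
    pos <- sort(sample(L, m))
    expect_equal(agesig:::gsea_es(w, pos), es_oracle(w, pos),
                 tolerance = 1e-12)
  }
})

test_that("the enrichment score matches the reference pre-ranked implementation", {
  skip_if_not_installed("fgsea")
  set.seed(31)
  for (rep in 1:10) {
    rho <- sort(runif(40, -1, 1), decreasing = TRUE)
    pos <- sort(sample(40, 6))
    expect_equal(agesig:::gsea_es(abs(rho), pos),
                 fgsea::calcGseaStat(rho, pos, gseaParam = 1),
                 tolerance = 1e-12)
  }
})

test_that("extreme set placements give boundary enrichment scores", {
  ranked <- tibble::tibble(
    tf = "f", target = paste0("g", 1:10),
    rho = seq(1, -1, length.out = 10)
  )
  top1 <- preranked_gsea(ranked, "f|g1", n_perm = 50, seed = 1)
  expect_equal(top1$es, 1, tolerance = 1e-12)
  bottom <- preranked_gsea(ranked, paste0("f|g", 8:10), n_perm = 50, seed = 1)
  expect_lt(bottom$es, 0)
  expect_error(preranked_gsea(ranked, paste0("f|g", 1:10)),
               class = "agesig_input_error")
  expect_error(preranked_gsea(ranked, "f|absent"),
               class = "agesig_input_error")
})

test_that("the score depends on correlations only through their ranks", {
  set.seed(33)
  ranked <- tibble::tibble(
    tf = "f", target = paste0("g", 1:30),
    rho = sort(runif(30, 0, 1), decreasing = TRUE)
  )
  set_keys <- paste0("f|g", c(2, 5, 9, 11, 20))
  a <- preranked_gsea(ranked, set_keys, n_perm = 200, seed = 5)
  doubled <- dplyr::mutate(ranked, rho = rho * 2)
  b <- preranked_gsea(doubled, set_keys, n_perm = 200, seed = 5)
  expect_equal(a$es, b$es, tolerance = 1e-12)
  expect_equal(a$p, b$p)
})

test_that("target sets enforce the five-interaction floor per regulator", {
  retained <- tibble::tibble(pathway = c("P1", "P2"),
                             class = "linear_up", n_contexts = 2L,
                             contexts = "x")
  systems <- tibble::tibble(pathway = c("P1", "P2"), system = "SYS")
  sets <- list(P1 = paste0("g", 1:10), P2 = paste0("g", 11:15))
  classes <- tidyr::expand_grid(
    tissue = c("t1", "t2"), gene_id = paste0("g", 1:15)
  ) |> dplyr::mutate(label = "linear_up")
  inter <- tibble::tibble(
    tf = c(rep("f5", 5), rep("f4", 4), rep("f7", 7)),
    target = c(paste0("g", 1:5), paste0("g", 1:4),
               c(paste0("g", 5:9), "x1", "x2"))
  )
  out <- build_target_sets(retained, classes, sets, systems, inter)
  expect_setequal(out$tf, c("f5", "f7"))
  expect_equal(out$set_size[out$tf == "f5"], 5)
  # f7 has 7 interactions but only 5 with relevant targets
  expect_equal(out$set_size[out$tf == "f7"], 5)
  expect_error(build_target_sets(retained, classes, sets, NULL, inter),
               class = "agesig_input_error")

  # genes present in only one tissue are not "relevant"
  classes1 <- dplyr::filter(classes, tissue == "t1")
  out1 <- build_target_sets(retained, classes1, sets, systems, inter)
  expect_equal(nrow(out1), 0)
})

test_that("association rows are BH-adjusted and seed-reproducible", {
  set.seed(40)
  ranked <- tibble::tibble(
    tf = rep(c("f1", "f2"), each = 25),
    target = paste0("g", 1:50),
    rho = sort(runif(50, -1, 1), decreasing = TRUE)
  )
  target_sets <- tibble::tibble(
    tf = c("f1", "f2"), system = "SYS", class = "linear_up",
    set_size = 5L,
    interaction_ids = list(
      paste(ranked$tf[1:5], ranked$target[1:5], sep = "|"),
      paste(ranked$tf[30:34], ranked$target[30:34], sep = "|")
    )
  )
  a <- tf_association(ranked, target_sets, n_perm = 500, seed = 2)
  b <- tf_association(ranked, target_sets, n_perm = 500, seed = 2)
  expect_identical(a, b)
  expect_true(all(a$p_adj >= a$p))
  # the top-of-list set scores positive and beats the mid-list set
  expect_gt(a$es[a$tf == "f1"], 0)
  expect_lt(a$p[a$tf == "f1"], a$p[a$tf == "f2"])
})
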