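# Shared fixtures, built in code. The small study is cached per test run.

.fixture_env <- new.env(parent = emptyenv())

small_study <- function() {
  if (is.null(.fixture_env$study)) {
    .fixture_env$study <- sim_study(n_genes = 300, n_per_group = 4, seed = 7)
  }
  .fixture_env$study
}

# truth/classes helper: label a truth table the way the classifier would
# if recovery were perfect (used to feed downstream stages directly)
truth_to_classes <- function(truth, tissue = "t1") {
  label <- dplyr::case_when(
    truth$true_class == "null" ~ "not_age_related",
    truth$true_class == "linear" & truth$direction == "up" ~ "linear_up",
    truth$true_class == "linear" ~ "linear_down",
    TRUE ~ paste0(
      agesig::stage_logistic(truth$inflection_c),
      ifelse(truth$direction == "up", "_up", "_down")
    )
  )
  tibble::tibble(gene_id = truth$gene_id, label = label, tissue = tissue)
}

# brute-force upper-tail hypergeometric by direct choose() summation
hyper_oracle <- function(k, n, K, N) {
  if (k <= 0) return(1)
  i <- seq(k, min(n, K))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# hand-rolled GSEA running sum, walked element by element
es_oracle <- function(w, pos) {
  L <- length(w)
  hit <- seq_len(L) %in% pos
  inc <- ifelse(hit, w / sum(w[pos]), 0)
  dec <- ifelse(hit, 0, 1 / (L - length(pos)))
  run <- cumsum(inc - dec)
  run[which.max(abs(run))]
}
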