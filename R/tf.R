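#' Filter regulator-target interactions to age-related whitelisted pairs
#'
#' Keeps an interaction iff the regulator is on the supplied whitelist
#' (e.g. DNA-binding transcription-factor GO terms) and both the regulator
#' and the target are age-related in at least one tissue.
#'
#' @param interactions Tibble (`tf`, `target`).
#' @param whitelist Character vector of admissible regulator ids.
#' @param age_related Character vector of genes age-related in >= 1 tissue.
#' @return The filtered, de-duplicated interaction tibble.
#' @export
filter_interactions <- function(interactions, whitelist, age_related) {
  if (length(whitelist) == 0) {
    warn("empty regulator whitelist; no interactions retained")
    return(interactions[0, ])
  }
  interactions %>%
    distinct(.data$tf, .data$target) %>%
    filter(.data$tf %in% whitelist,
           .data$tf %in% age_related,
           .data$target %in% age_related)
}

#' Rank interactions by regulator-target Spearman correlation
#'
#' Spearman rho (average ranks on ties) between the regulator's and the
#' target's log2-CPM across all supplied samples, sorted decreasing with
#' lexicographic (tf, target) tie-breaking. Pairs involving a constant
#' expression vector are dropped with a warning.
#'
#' @param expr A [log2_cpm()] tibble covering all samples to pool.
#' @param interactions Tibble (`tf`, `target`); both genes must be rows of
#'   `expr`.
#' @return Tibble (`tf`, `target`, `rho`), one row per surviving pair.
#' @export
rank_by_spearman <- function(expr, interactions) {
  m <- expr_matrix(expr)
  genes <- unique(c(interactions$tf, interactions$target))
  missing <- setdiff(genes, rownames(m))
  if (length(missing) > 0) {
    abort(paste0("interaction genes absent from expression: ",
                 paste(head(missing, 5), collapse = ", ")),
          class = "agesig_input_error")
  }
  rk <- t(apply(m[genes, , drop = FALSE], 1, rank))
  const <- apply(m[genes, , drop = FALSE], 1, function(v) sd(v) == 0)
  drop <- interactions$tf %in% genes[const] |
    interactions$target %in% genes[const]
  if (any(drop)) {
    warn(sprintf("dropping %d interactions with constant expression", sum(drop)))
  }
  keep <- interactions[!drop, ]
  rho <- vapply(seq_len(nrow(keep)), function(i) {
    cor(rk[keep$tf[i], ], rk[keep$target[i], ])
  }, numeric(1))
  keep %>%
    mutate(rho = rho) %>%
    arrange(dplyr::desc(.data$rho), .data$tf, .data$target)
}

#' Build per-regulator interaction sets for enriched level-2 systems
#'
#' For each retained pathway x class the pathway's level-2 system is looked
#' up; the system's "relevant" genes are those carrying that exact class
#' label in at least `min_tissues` tissues of the species and annotated to
#' any pathway of the system. A regulator's set is its filtered interactions
#' whose target is relevant; sets smaller than `min_targets` are dropped.
#'
#' @param retained Output of [cross_context_filter()].
#' @param classes_tbl Classes with `tissue`, `gene_id`, `label` (one species).
#' @param sets Gene-set collection of the species.
#' @param systems Tibble (`pathway`, `system`) mapping pathways to level-2
#'   systems.
#' @param interactions Filtered interactions (`tf`, `target`).
#' @param min_tissues Tissue-sharing requirement on relevant genes.
#' @param min_targets Minimum interactions per regulator set (default 5).
#' @return Tibble: `tf`, `system`, `class`, `set_size`, `interaction_ids`
#'   (list of `tf|target` keys).
#' @export
build_target_sets <- function(retained, classes_tbl, sets, systems,
                              interactions, min_tissues = 2, min_targets = 5) {
  if (is.null(systems) || !all(c("pathway", "system") %in% names(systems))) {
    abort("a pathway -> level-2 system mapping is required",
          class = "agesig_input_error")
  }
  ret_sys <- retained %>%
    left_join(systems, by = "pathway") %>%
    filter(!is.na(.data$system)) %>%
    distinct(.data$system, .data$class)
  out <- list()
  shared <- classes_tbl %>%
    filter(.data$label != "not_age_related") %>%
    distinct(.data$gene_id, .data$label, .data$tissue) %>%
    count(.data$gene_id, .data$label, name = "n_tissues") %>%
    filter(.data$n_tissues >= min_tissues)
  for (i in seq_len(nrow(ret_sys))) {
    sys <- ret_sys$system[i]; cl <- ret_sys$class[i]
    sys_paths <- systems$pathway[systems$system == sys]
    sys_genes <- unique(unlist(sets[intersect(sys_paths, names(sets))]))
    relevant <- intersect(
      shared$gene_id[shared$label == cl], sys_genes
    )
    if (length(relevant) == 0) next
    hits <- interactions %>% filter(.data$target %in% relevant)
    if (nrow(hits) == 0) next
    for (f in unique(hits$tf)) {
      sub <- hits %>% filter(.data$tf == f)
      if (nrow(sub) < min_targets) next
      out[[length(out) + 1]] <- tibble(
        tf = f, system = sys, class = cl, set_size = nrow(sub),
        interaction_ids = list(paste(sub$tf, sub$target, sep = "|"))
      )
    }
  }
  bind_rows(out)
}

# Enrichment score of a hit-position set within a ranked, weighted list.
# w: |rho| of the full ranked list; pos: sorted hit positions.
gsea_es <- function(w, pos) {
  L <- length(w); m <- length(pos)
  if (m >= L) abort("set covers the whole ranked list",
                    class = "agesig_input_error")
  hw <- w[pos]
  tot <- sum(hw)
  if (tot <= 0) hw <- rep(1, m) else hw <- hw / tot
  if (tot <= 0) hw <- hw / m
  cum <- cumsum(hw)
  d <- (pos - seq_len(m)) / (L - m)
  after <- cum - d
  before <- c(0, cum[-m]) - d
  max_pos <- max(after)
  min_neg <- min(before)
  if (max_pos >= abs(min_neg)) max_pos else min_neg
}

#' Pre-ranked GSEA of one interaction set
#'
#' Walks the Spearman-ranked interaction list; hits increment the running
#' sum by `|rho| / sum(|rho| over the set)`, misses decrement it by
#' `1 / (L - m)`. The enrichment score is the maximal deviation from zero.
#' The p-value is the one-sided Monte-Carlo probability of an `|ES|` at
#' least as extreme among `n_perm` uniformly drawn same-size sets.
#'
#' @param ranked A [rank_by_spearman()] tibble.
#' @param set Character vector of `tf|target` interaction keys (>= 5, and a
#'   strict subset of the list).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the permutation draws.
#' @return List with `es`, `p`, `leading_edge` (interaction keys up to the
#'   ES extremum), and `set_size`.
#' @export
preranked_gsea <- function(ranked, set, n_perm = 10000, seed = 1L) {
  keys <- paste(ranked$tf, ranked$target, sep = "|")
  pos <- match(set, keys)
  if (length(pos) == 0 || anyNA(pos)) {
    abort("set contains interactions absent from the ranked list",
          class = "agesig_input_error")
  }
  pos <- sort(pos)
  L <- length(keys); m <- length(pos)
  if (m >= L) abort("set covers the whole ranked list",
                    class = "agesig_input_error")
  w <- abs(ranked$rho)
  es <- gsea_es(w, pos)

  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    gsea_es(w, sort(sample.int(L, m)))
  }, numeric(1))
  p <- (1 + sum(abs(perm) >= abs(es))) / (1 + n_perm)

  # leading edge: hits at or before the running-sum extremum
  hw <- w[pos]; tot <- sum(hw)
  hw <- if (tot > 0) hw / tot else rep(1 / m, m)
  cum <- cumsum(hw)
  d <- (pos - seq_len(m)) / (L - m)
  if (es >= 0) {
    peak <- which.max(cum - d)
    le <- keys[pos[seq_len(peak)]]
  } else {
    peak <- which.min(c(0, cum[-m]) - d)
    le <- keys[pos[pos >= pos[peak]]]
  }
  list(es = es, p = p, leading_edge = le, set_size = m)
}

#' Associate regulators with enriched level-2 systems
#'
#' Runs [preranked_gsea()] on every regulator x system interaction set and
#' adjusts the permutation p-values with Benjamini-Hochberg across rows.
#'
#' @param ranked A [rank_by_spearman()] tibble.
#' @param target_sets Output of [build_target_sets()].
#' @param n_perm,seed Passed to [preranked_gsea()]; each row's permutations
#'   are seeded deterministically from `seed`.
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return Tibble: `tf`, `system`, `class`, `set_size`, `es`, `p`, `p_adj`,
#'   `significant`, `leading_edge` (list).
#' @export
tf_association <- function(ranked, target_sets, n_perm = 10000, seed = 1L,
                           alpha = 0.05) {
  if (nrow(target_sets) == 0) {
    return(tibble(tf = character(), system = character(), class = character(),
                  set_size = integer(), es = numeric(), p = numeric(),
                  p_adj = numeric(), significant = logical(),
                  leading_edge = list()))
  }
  res <- lapply(seq_len(nrow(target_sets)), function(i) {
    g <- preranked_gsea(ranked, target_sets$interaction_ids[[i]],
                        n_perm = n_perm, seed = seed + i)
    tibble(
      tf = target_sets$tf[i], system = target_sets$system[i],
      class = target_sets$class[i], set_size = g$set_size,
      es = g$es, p = g$p, leading_edge = list(g$leading_edge)
    )
  })
  out <- bind_rows(res)
  out %>%
    mutate(p_adj = p.adjust(.data$p, method = "BH"),
           significant = .data$p_adj < alpha) %>%
    select("tf", "system", "class", "set_size", "es", "p", "p_adj",
           "significant", "leading_edge")
}
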