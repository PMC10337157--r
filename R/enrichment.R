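#' Pathway over-representation for one trajectory-class gene list
#'
#' One-sided Fisher's exact (hypergeometric upper-tail) test of each pathway
#' against the class list within the expression universe. Set members absent
#' from the universe are removed first. Pathways overlapping the class list
#' by fewer than `min_overlap` genes are discarded untested and excluded
#' from the Bonferroni family; the family is the tested pathways within this
#' call (one tissue x class).
#'
#' @param class_genes Character vector, the trajectory-class gene list.
#' @param universe Character vector, the stratum's expression universe.
#' @param sets Named list of pathway member vectors.
#' @param min_overlap Minimum class-list overlap to test (default 5).
#' @param alpha Significance level on the Bonferroni-adjusted p (default 0.01).
#' @param tissue,species,class_label Optional context stamped on each row.
#' @return Tibble: `pathway`, context columns, `overlap_genes` (list),
#'   `k`, `K`, `n`, `N`, `tested`, `p`, `p_adj`, `significant`.
#' @export
pathway_enrich <- function(class_genes, universe, sets, min_overlap = 5,
                           alpha = 0.01, tissue = NA_character_,
                           species = NA_character_,
                           class_label = NA_character_) {
  universe <- unique(universe)
  if (length(universe) == 0) {
    abort("empty universe", class = "agesig_input_error")
  }
  class_genes <- intersect(unique(class_genes), universe)
  n <- length(class_genes)
  N <- length(universe)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    ov <- intersect(members, class_genes)
    k <- length(ov); K <- length(members)
    tested <- k >= min_overlap
    p <- if (tested) {
      phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    } else NA_real_
    tibble(pathway = nm, species = species, tissue = tissue,
           class = class_label, overlap_genes = list(ov),
           k = k, K = K, n = n, N = N, tested = tested, p = p)
  })
  out <- bind_rows(rows)
  n_tested <- sum(out$tested)
  out %>%
    mutate(
      p_adj = ifelse(.data$tested, pmin(1, .data$p * n_tested), NA_real_),
      significant = !is.na(.data$p_adj) & .data$p_adj < alpha
    )
}

#' Retain pathways enriched in two or more contexts
#'
#' A pathway x class pair survives iff it is significantly enriched in at
#' least `min_contexts` contexts, where a context is a tissue of either
#' species (the filter is applied per class panel, so linear-up hits are
#' matched with linear-up hits).
#'
#' @param enrich_tbl Row-bound [pathway_enrich()] tables carrying `species`,
#'   `tissue`, `class` columns.
#' @param min_contexts Minimum number of distinct (species, tissue) contexts.
#' @return Tibble: `pathway`, `class`, `n_contexts`, `contexts`.
#' @export
cross_context_filter <- function(enrich_tbl, min_contexts = 2) {
  enrich_tbl %>%
    filter(.data$significant) %>%
    mutate(context = paste(.data$species, .data$tissue, sep = ":")) %>%
    group_by(.data$pathway, .data$class) %>%
    summarise(
      n_contexts = dplyr::n_distinct(.data$context),
      contexts = paste(sort(unique(.data$context)), collapse = ","),
      .groups = "drop"
    ) %>%
    filter(.data$n_contexts >= min_contexts)
}

#' Tabulate the circle-summary statistics for retained pathways
#'
#' For each retained pathway x class, tissue and contrast age: the number of
#' that tissue's age-related genes of the class annotated to the pathway,
#' binned small (0-5), medium (6-15) or large (>15), and the geometric-mean
#' fold change of those genes versus the reference age (display saturation
#' at 4-fold recorded in `fold_cap`).
#'
#' @param retained Output of [cross_context_filter()].
#' @param classes_tbl Trajectory classes with `species`, `tissue`, `gene_id`,
#'   `label` columns.
#' @param de_tbl [call_de()] output with `species`, `tissue` columns.
#' @param sets_by_species Named list (per species) of gene-set collections.
#' @return Tibble: `pathway`, `class`, `species`, `tissue`, `contrast_age`,
#'   `n_genes`, `bin`, `mean_log2_fc`, `mean_fold`, `fold_cap`.
#' @export
circle_summarize <- function(retained, classes_tbl, de_tbl, sets_by_species) {
  if (nrow(retained) == 0) {
    return(tibble(pathway = character(), class = character(),
                  species = character(), tissue = character(),
                  contrast_age = numeric(), n_genes = integer(),
                  bin = character(), mean_log2_fc = numeric(),
                  mean_fold = numeric(), fold_cap = numeric()))
  }
  strata <- distinct(classes_tbl, .data$species, .data$tissue)
  ages_by_stratum <- de_tbl %>%
    distinct(.data$species, .data$tissue, .data$contrast_age)
  out <- list()
  for (i in seq_len(nrow(retained))) {
    pw <- retained$pathway[i]; cl <- retained$class[i]
    for (j in seq_len(nrow(strata))) {
      sp <- strata$species[j]; ti <- strata$tissue[j]
      members <- sets_by_species[[sp]][[pw]]
      if (is.null(members)) next
      genes <- classes_tbl$gene_id[classes_tbl$species == sp &
                                     classes_tbl$tissue == ti &
                                     classes_tbl$label == cl]
      genes <- intersect(genes, members)
      ages <- ages_by_stratum$contrast_age[ages_by_stratum$species == sp &
                                             ages_by_stratum$tissue == ti]
      for (a in sort(ages)) {
        fc <- de_tbl$log2_fc[de_tbl$species == sp & de_tbl$tissue == ti &
                               de_tbl$contrast_age == a &
                               de_tbl$gene_id %in% genes]
        nl <- length(genes)
        out[[length(out) + 1]] <- tibble(
          pathway = pw, class = cl, species = sp, tissue = ti,
          contrast_age = a, n_genes = nl,
          bin = circle_bin(nl),
          mean_log2_fc = if (nl > 0) mean(fc) else NA_real_,
          mean_fold = if (nl > 0) 2^mean(fc) else NA_real_,
          fold_cap = 4
        )
      }
    }
  }
  bind_rows(out)
}

circle_bin <- function(n) {
  ifelse(n <= 5, "small", ifelse(n <= 15, "medium", "large"))
}
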