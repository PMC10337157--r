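#' Default pipeline parameters
#'
#' One place for every tunable of the full run; any element can be
#' overridden through the `params` argument of [run_pipeline()] or a YAML
#' file read with [read_pipeline_config()].
#'
#' @return Named list of parameters with documented defaults.
#' @export
pipeline_params <- function() {
  list(
    prior_count = 0.5,       # log2-CPM pseudo-count
    fc_threshold = 1.5,      # DE fold-change gate
    de_alpha = 0.05,         # DE Bonferroni-adjusted p gate
    de_family = "per_contrast",
    moderation = TRUE,       # empirical-Bayes variance moderation
    evidence_cutoff = 6,     # BIC gap to the null model
    linear_priority = 2,     # BIC gap logistic must beat linear by
    stage_bounds = c(12, 21),
    rss_floor = 1e-12,
    min_overlap = 5,         # enrichment overlap discard
    enrich_alpha = 0.01,     # enrichment Bonferroni gate
    min_contexts = 2,        # cross-tissue retention filter
    min_tf_targets = 5,
    tf_min_tissues = 2,
    n_perm = 10000,          # GSEA permutations
    tf_alpha = 0.05
  )
}

#' Read a pipeline configuration file
#'
#' A single YAML file with two blocks: `params` (any [pipeline_params()]
#' key) and `inputs` (paths: per-species `counts`, `gene_sets`,
#' `interactions`, `whitelist`; shared `metadata`, `orthologs`, `systems`),
#' plus optional `seed` and `out_dir`.
#'
#' @param path Path to the YAML file.
#' @return A named list with `params` merged over the defaults.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  params <- pipeline_params()
  for (nm in names(cfg$params %||% list())) {
    if (!nm %in% names(params)) {
      abort(paste0("unknown parameter key: ", nm),
            class = "agesig_config_error")
    }
    params[[nm]] <- cfg$params[[nm]]
  }
  cfg$params <- params
  cfg
}

#' Load the input artifacts named by a configuration into a study object
#'
#' @param config Output of [read_pipeline_config()].
#' @return An `aging_study`-shaped list usable by [run_pipeline()].
#' @export
load_study <- function(config) {
  inp <- config$inputs
  metadata <- readr::read_tsv(inp$metadata, show_col_types = FALSE)
  species <- names(inp$counts)
  counts <- list(); sets <- list(); inter <- list(); wl <- list()
  for (sp in species) {
    cm <- read_counts(inp$counts[[sp]], metadata)
    counts[[sp]] <- cm$counts
    sets[[sp]] <- read_gmt(inp$gene_sets[[sp]])
    inter[[sp]] <- read_pairs(inp$interactions[[sp]], kind = "interaction")
    wl[[sp]] <- readLines(inp$whitelist[[sp]])
  }
  orthologs <- if (!is.null(inp$orthologs)) {
    read_pairs(inp$orthologs, kind = "ortholog")
  } else NULL
  systems <- if (!is.null(inp$systems)) {
    readr::read_tsv(inp$systems, show_col_types = FALSE)
  } else NULL
  structure(
    list(counts = counts, metadata = metadata, gene_sets = sets,
         systems = systems, orthologs = orthologs, interactions = inter,
         whitelist = wl, seed = config$seed %||% 1L),
    class = "aging_study"
  )
}

#' Run the full aging-signature pipeline
#'
#' Executes the flowchart on a study object: per stratum (species x sex x
#' tissue) log2-CPM normalisation, DE gating versus the youngest age, BIC
#' trajectory classification; then pathway enrichment per stratum and class,
#' the cross-context retention filter and circle summaries; cross-species
#' ortholog direction concordance when two species are present; and
#' regulator association per species via Spearman-ranked pre-ranked GSEA.
#'
#' @param study An `aging_study` from [sim_study()] or [load_study()].
#' @param params Named list overriding [pipeline_params()] entries.
#' @param out_dir Optional directory; when given, all result tables and a
#'   manifest are written there with [write_results()].
#' @param seed Seed for the GSEA permutations (the only stochastic stage);
#'   defaults to the study's own seed.
#' @return An `aging_pipeline` list of result tibbles: `de_table`,
#'   `trajectory_fits`, `trajectory_classes`, `class_counts`, `enrichment`,
#'   `retained_pathways`, `circle_summary`, `concordance`, `tf_association`,
#'   plus `log` and `params`.
#' @export
run_pipeline <- function(study, params = list(), out_dir = NULL, seed = NULL) {
  stopifnot(inherits(study, "aging_study") || is.list(study))
  p <- pipeline_params()
  for (nm in names(params)) {
    if (!nm %in% names(p)) {
      abort(paste0("unknown parameter key: ", nm),
            class = "agesig_config_error")
    }
    p[[nm]] <- params[[nm]]
  }
  seed <- seed %||% study$seed %||% 1L
  log_lines <- character()
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    rlang::inform(line)
  }

  species <- names(study$counts)
  de_all <- list(); classes_all <- list(); fits_all <- list()
  counts_by_class <- list(); enrich_all <- list()
  logcpm_by_species <- list(); universe_by_species <- list()

  for (sp in species) {
    wide <- study$counts[[sp]]
    meta_sp <- filter(study$metadata, .data$species == sp)
    strata <- distinct(meta_sp, .data$sex, .data$tissue)
    for (i in seq_len(nrow(strata))) {
      sx <- strata$sex[i]; ti <- strata$tissue[i]
      meta <- filter(meta_sp, .data$sex == sx, .data$tissue == ti)
      sub <- wide[, c("gene_id", meta$sample_id)]
      keep <- rowSums(as.matrix(sub[-1])) > 0
      sub <- sub[keep, ]
      lc <- log2_cpm(sub, prior = p$prior_count)
      de <- fit_all_contrasts(lc, meta, moderation = p$moderation) %>%
        call_de(fc_threshold = p$fc_threshold, alpha = p$de_alpha,
                family = p$de_family)
      tr <- classify_trajectories(
        lc, meta, de_universe(de),
        evidence_cutoff = p$evidence_cutoff,
        linear_priority = p$linear_priority,
        stage_bounds = p$stage_bounds, rss_floor = p$rss_floor
      )
      say("stratum %s/%s/%s: %d genes, %d DE, %d age-related",
          sp, sx, ti, nrow(sub), length(de_universe(de)),
          sum(tr$classes$label != "not_age_related"))
      ctx <- function(tbl) mutate(tbl, species = sp, sex = sx, tissue = ti)
      de_all[[length(de_all) + 1]] <- ctx(de)
      classes_all[[length(classes_all) + 1]] <- ctx(tr$classes)
      if (!is.null(tr$fits)) fits_all[[length(fits_all) + 1]] <- ctx(tr$fits)
      counts_by_class[[length(counts_by_class) + 1]] <- ctx(tr$counts)
      for (cl in AGE_CLASSES) {
        genes <- tr$classes$gene_id[tr$classes$label == cl]
        if (length(genes) == 0) next
        enrich_all[[length(enrich_all) + 1]] <- pathway_enrich(
          genes, sub$gene_id, study$gene_sets[[sp]],
          min_overlap = p$min_overlap, alpha = p$enrich_alpha,
          tissue = ti, species = sp, class_label = cl
        )
      }
    }
    # pooled log2-CPM across all the species' samples for the regulator stage
    keep_sp <- rowSums(as.matrix(wide[-1])) > 0
    logcpm_by_species[[sp]] <- log2_cpm(wide[keep_sp, ], prior = p$prior_count)
    universe_by_species[[sp]] <- wide$gene_id
  }

  de_table <- bind_rows(de_all)
  classes <- bind_rows(classes_all)
  fits <- bind_rows(fits_all)
  class_counts <- bind_rows(counts_by_class)
  enrichment <- bind_rows(enrich_all)
  retained <- if (nrow(enrichment) > 0) {
    cross_context_filter(enrichment, min_contexts = p$min_contexts)
  } else {
    tibble(pathway = character(), class = character(),
           n_contexts = integer(), contexts = character())
  }
  n_tested <- if ("tested" %in% names(enrichment)) sum(enrichment$tested) else 0L
  say("enrichment: %d tested rows, %d retained pathway x class",
      n_tested, nrow(retained))
  circle <- circle_summarize(retained, classes, de_table, study$gene_sets)

  sp_a <- species[1]
  sp_b <- if (length(species) >= 2) species[2] else NA_character_
  concordance <- if (length(species) >= 2 && !is.null(study$orthologs) &&
                     nrow(study$orthologs) > 0) {
    ortholog_concordance(
      filter(classes, .data$species == .env$sp_a),
      filter(classes, .data$species == .env$sp_b),
      study$orthologs
    )
  } else {
    say("concordance stage skipped (needs two species and an ortholog map)")
    tibble(orientation = character(), tissue = character(),
           direction = character(), n_query = integer(),
           k_concordant = integer(), K_target = integer(),
           N_total = integer(), p = numeric(), degenerate = logical())
  }

  tf_rows <- list()
  for (k in seq_along(species)) {
    sp <- species[k]
    inter <- study$interactions[[sp]]
    wl <- study$whitelist[[sp]]
    if (is.null(inter) || is.null(wl) || nrow(retained) == 0) next
    cls_sp <- filter(classes, .data$species == .env$sp)
    age_rel <- unique(cls_sp$gene_id[cls_sp$label != "not_age_related"])
    filt <- filter_interactions(inter, wl, age_rel)
    if (nrow(filt) == 0) next
    ranked <- rank_by_spearman(logcpm_by_species[[sp]], filt)
    sets_tf <- build_target_sets(
      retained, cls_sp, study$gene_sets[[sp]], study$systems, filt,
      min_tissues = p$tf_min_tissues, min_targets = p$min_tf_targets
    )
    if (nrow(sets_tf) == 0) next
    assoc <- tf_association(ranked, sets_tf, n_perm = p$n_perm,
                            seed = seed + 1000 * k, alpha = p$tf_alpha)
    tf_rows[[length(tf_rows) + 1]] <- mutate(assoc, species = sp)
    say("tf association (%s): %d regulator x system rows", sp, nrow(assoc))
  }
  tf_assoc <- if (length(tf_rows) > 0) bind_rows(tf_rows) else {
    tibble(tf = character(), system = character(), class = character(),
           set_size = integer(), es = numeric(), p = numeric(),
           p_adj = numeric(), significant = logical(),
           leading_edge = list(), species = character())
  }

  result <- structure(
    list(
      de_table = de_table,
      trajectory_fits = fits,
      trajectory_classes = classes,
      class_counts = class_counts,
      enrichment = enrichment,
      retained_pathways = retained,
      circle_summary = circle,
      concordance = concordance,
      tf_association = tf_assoc,
      params = p, seed = seed, log = log_lines
    ),
    class = "aging_pipeline"
  )
  if (!is.null(out_dir)) {
    tables <- result[c("de_table", "trajectory_fits", "trajectory_classes",
                       "class_counts", "enrichment", "retained_pathways",
                       "circle_summary", "concordance", "tf_association")]
    write_results(tables, out_dir, config = p, seed = seed)
  }
  result
}

#' @export
print.aging_pipeline <- function(x, ...) {
  cat("<aging_pipeline>\n")
  cat("  age-related genes:",
      sum(x$trajectory_classes$label != "not_age_related"), "\n")
  cat("  retained pathways:", nrow(x$retained_pathways), "\n")
  cat("  concordance rows:", nrow(x$concordance), "\n")
  cat("  regulator rows:", nrow(x$tf_association), "\n")
  invisible(x)
}

#' @method glance aging_pipeline
#' @export
glance.aging_pipeline <- function(x, ...) {
  tibble(
    n_strata = nrow(distinct(x$trajectory_classes, .data$species,
                             .data$sex, .data$tissue)),
    n_de_rows = nrow(x$de_table),
    n_age_related = sum(x$trajectory_classes$label != "not_age_related"),
    n_retained_pathways = dplyr::n_distinct(x$retained_pathways$pathway),
    n_concordance_tests = sum(!x$concordance$degenerate %||% logical(0)),
    n_tf_significant = sum(x$tf_association$significant %||% logical(0))
  )
}

#' @method tidy aging_pipeline
#' @export
tidy.aging_pipeline <- function(x, ...) {
  x$trajectory_classes
}

#' Summarise a completed run the way the study's figures do
#'
#' Per-stratum class counts, counts of genes shared by two or more tissues
#' of a species with the same direction and the same broad classification
#' (linear vs logistic), the retained pathways and the circle summary.
#' Accepts either an in-memory `aging_pipeline` or an output directory
#' written by [run_pipeline()].
#'
#' @param x An `aging_pipeline`, or the path to its `out_dir`.
#' @return List of tibbles: `class_counts`, `shared_genes`,
#'   `retained_pathways`, `circle_summary`.
#' @export
pipeline_report <- function(x) {
  if (is.character(x)) {
    need <- c("trajectory_classes", "class_counts", "retained_pathways",
              "circle_summary")
    paths <- file.path(x, paste0(need, ".tsv"))
    missing <- need[!file.exists(paths)]
    if (length(missing) > 0) {
      abort(paste0("missing stage outputs: ", paste(missing, collapse = ", ")),
            class = "agesig_input_error")
    }
    x <- setNames(lapply(paths, readr::read_tsv, show_col_types = FALSE), need)
  }
  shared <- x$trajectory_classes %>%
    filter(.data$label != "not_age_related") %>%
    mutate(
      family = ifelse(grepl("^linear", .data$label), "linear", "logistic"),
      direction = class_direction(.data$label)
    ) %>%
    distinct(.data$species, .data$gene_id, .data$family, .data$direction,
             .data$tissue) %>%
    count(.data$species, .data$gene_id, .data$family, .data$direction,
          name = "n_tissues") %>%
    filter(.data$n_tissues >= 2) %>%
    count(.data$species, .data$family, .data$direction, name = "n_genes")
  list(
    class_counts = x$class_counts,
    shared_genes = shared,
    retained_pathways = x$retained_pathways,
    circle_summary = x$circle_summary
  )
}
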