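#' Describe a simulated aging time-course design
#'
#' Captures the sampling design of a rodent aging RNA-seq study: the age
#' groups (months), the number of animals per group, sequencing depth, and
#' the mixture of planted trajectory classes. Defaults follow the mouse
#' design of a multi-tissue lifespan study (ages 6, 12, 18, 21, 24 and 27
#' months); `rat_mode = TRUE` adds the 9-month group used for rats.
#'
#' @param ages Numeric vector of age groups in months, strictly increasing.
#' @param n_per_group Animals (samples) per age group.
#' @param n_genes Number of genes to simulate.
#' @param fractions Length-3 proportions of null / linear / logistic genes;
#'   must sum to 1.
#' @param lib_log_mean,lib_log_sd Log-scale mean and sd of the log-normal
#'   library-size distribution. The default depth (`exp(lib_log_mean)` = 2e7)
#'   is typical of bulk RNA-seq.
#' @param dispersion_meanlog,dispersion_sdlog Log-normal parameters of the
#'   gene-wise negative-binomial dispersion; the default median is 0.05.
#' @param slope Magnitude of the linear slope in log2-CPM per month.
#' @param amplitude Total log2-CPM change of a logistic gene between its
#'   plateaus.
#' @param p_up Probability that a planted trajectory goes up rather than down.
#' @param rat_mode If `TRUE`, insert a 9-month group after the reference age.
#' @return A `sim_design` list.
#' @examples
#' d <- sim_design(n_genes = 100, n_per_group = 4)
#' d$ages
#' @export
sim_design <- function(ages = c(6, 12, 18, 21, 24, 27),
                       n_per_group = 10,
                       n_genes = 5000,
                       fractions = c(null = 0.8, linear = 0.1, logistic = 0.1),
                       lib_log_mean = log(2e7),
                       lib_log_sd = 0.2,
                       dispersion_meanlog = log(0.05),
                       dispersion_sdlog = 0.5,
                       slope = 0.05,
                       amplitude = 2,
                       p_up = 0.5,
                       rat_mode = FALSE) {
  if (rat_mode && !9 %in% ages) ages <- sort(c(ages, 9))
  if (length(ages) < 2 || is.unsorted(ages, strictly = TRUE)) {
    abort("`ages` must be strictly increasing with >= 2 groups",
          class = "agesig_config_error")
  }
  fractions <- unname(fractions)
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    abort("`fractions` must be 3 nonnegative proportions of null/linear/logistic genes summing to 1",
          class = "agesig_config_error")
  }
  if (n_per_group < 1 || n_genes < 1) {
    abort("`n_per_group` and `n_genes` must be positive",
          class = "agesig_config_error")
  }
  structure(
    list(
      ages = ages, n_per_group = n_per_group, n_genes = n_genes,
      fractions = setNames(fractions, c("null", "linear", "logistic")),
      lib_log_mean = lib_log_mean, lib_log_sd = lib_log_sd,
      dispersion_meanlog = dispersion_meanlog,
      dispersion_sdlog = dispersion_sdlog,
      slope = slope, amplitude = amplitude, p_up = p_up
    ),
    class = "sim_design"
  )
}

#' Draw a ground-truth gene table for a simulated design
#'
#' Assigns each gene a trajectory class (null / linear / logistic), a
#' direction, and generative parameters: baseline log2-CPM, NB dispersion,
#' linear slope or logistic inflection/steepness/amplitude. Class counts are
#' deterministic (largest-remainder rounding of the design fractions); which
#' genes get which class is randomised under `seed`.
#'
#' @param design A [sim_design()].
#' @param seed Integer seed; the table is a pure function of (design, seed).
#' @param prefix Gene-id prefix, e.g. `"mm_"`.
#' @return A tibble with one row per gene: `gene_id`, `true_class`,
#'   `direction`, `slope`, `inflection_c`, `hill_b`, `amplitude`,
#'   `baseline_log2cpm`, `dispersion`.
#' @examples
#' tr <- sim_truth(sim_design(n_genes = 50, fractions = c(0.8, 0.1, 0.1)), seed = 1)
#' table(tr$true_class)
#' @export
sim_truth <- function(design, seed = 1L, prefix = "g") {
  stopifnot(inherits(design, "sim_design"))
  set.seed(seed)
  n <- design$n_genes
  # largest-remainder apportionment so class counts match fractions exactly
  raw <- design$fractions * n
  base_n <- floor(raw)
  rem <- n - sum(base_n)
  if (rem > 0) {
    extra <- order(raw - base_n, decreasing = TRUE)[seq_len(rem)]
    base_n[extra] <- base_n[extra] + 1
  }
  classes <- sample(rep(c("null", "linear", "logistic"), times = base_n))

  age_lo <- min(design$ages)
  age_hi <- max(design$ages)
  dir_draw <- ifelse(runif(n) < design$p_up, "up", "down")
  truth <- tibble(
    gene_id = sprintf("%sg%05d", prefix, seq_len(n)),
    true_class = classes,
    direction = ifelse(classes == "null", "none", dir_draw),
    slope = ifelse(
      classes == "linear",
      design$slope * ifelse(dir_draw == "up", 1, -1),
      NA_real_
    ),
    inflection_c = ifelse(
      classes == "logistic",
      runif(n, age_lo + 1, age_hi - 1),
      NA_real_
    ),
    hill_b = ifelse(
      classes == "logistic",
      runif(n, 0.5, 2) * ifelse(dir_draw == "up", 1, -1),
      NA_real_
    ),
    amplitude = ifelse(classes == "logistic", design$amplitude, NA_real_),
    baseline_log2cpm = pmax(0.5, rnorm(n, mean = 5, sd = 1.5)),
    dispersion = rlnorm(n, design$dispersion_meanlog, design$dispersion_sdlog)
  )
  truth
}

#' Four-parameter logistic curve
#'
#' `f(t) = A + (D - A) / (1 + exp(-b * (t - c)))` with lower plateau `A`,
#' upper plateau `D`, inflection age `c` (months) and Hill coefficient `b`.
#' With `D >= A` the sign of `b` alone encodes direction: positive `b`
#' increases with age. Shared by the generator and the trajectory fitter so
#' planted and fitted trajectories use the identical formula.
#'
#' @param t Ages in months.
#' @param A,D Lower and upper plateaus (log2-CPM).
#' @param c Inflection age in months.
#' @param b Hill (steepness) coefficient.
#' @return Numeric vector of trajectory values.
#' @examples
#' logistic4(c(6, 20, 27), A = 5, D = 7, c = 20, b = 1)
#' @export
logistic4 <- function(t, A, D, c, b) {
  A + (D - A) / (1 + exp(-b * (t - c)))
}

#' Evaluate the planted mean log2-CPM trajectory of truth-table genes
#'
#' @param truth A [sim_truth()] table (any subset of rows).
#' @param t Ages in months at which to evaluate.
#' @param ref_age Age at which linear genes sit at their baseline.
#' @return A matrix, genes x length(t), of mean log2-CPM values.
#' @export
truth_trajectory <- function(truth, t, ref_age = 6) {
  out <- matrix(NA_real_, nrow(truth), length(t),
                dimnames = list(truth$gene_id, NULL))
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    out[i, ] <- switch(
      row$true_class,
      null = rep(row$baseline_log2cpm, length(t)),
      linear = row$baseline_log2cpm + row$slope * (t - ref_age),
      logistic = {
        if (row$hill_b >= 0) {
          logistic4(t, A = row$baseline_log2cpm,
                    D = row$baseline_log2cpm + row$amplitude,
                    c = row$inflection_c, b = row$hill_b)
        } else {
          logistic4(t, A = row$baseline_log2cpm - row$amplitude,
                    D = row$baseline_log2cpm,
                    c = row$inflection_c, b = row$hill_b)
        }
      }
    )
  }
  out
}

#' Simulate negative-binomial counts from a truth table
#'
#' Counts for sample s, gene g are NB with mean
#' `libsize_s * 2^mu_g(age_s) / 1e6` and gene-wise dispersion phi_g
#' (variance `mu + phi * mu^2`), where mu_g(t) is the planted log2-CPM
#' trajectory. Library sizes are log-normal per the design.
#'
#' @param truth A [sim_truth()] table.
#' @param design The matching [sim_design()].
#' @param seed Integer seed.
#' @param species,sex,tissue Metadata values stamped on every sample.
#' @param sample_prefix Prefix for sample ids.
#' @return A list with `counts` (tibble: `gene_id` + one column per sample)
#'   and `metadata` (tibble: `sample_id`, `species`, `sex`, `tissue`,
#'   `age_months`).
#' @examples
#' d <- sim_design(n_genes = 20, n_per_group = 3)
#' sim <- sim_counts(sim_truth(d, seed = 1), d, seed = 2)
#' dim(sim$counts)
#' @export
sim_counts <- function(truth, design, seed = 1L,
                       species = "mouse", sex = "male", tissue = "gastrocnemius",
                       sample_prefix = NULL) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(seed)
  ages <- rep(design$ages, each = design$n_per_group)
  n_samp <- length(ages)
  if (is.null(sample_prefix)) {
    sample_prefix <- paste(substr(species, 1, 2), substr(tissue, 1, 3), sep = "_")
  }
  sample_ids <- sprintf("%s_s%03d", sample_prefix, seq_len(n_samp))
  libsize <- rlnorm(n_samp, design$lib_log_mean, design$lib_log_sd)

  mu_log2 <- truth_trajectory(truth, ages, ref_age = min(design$ages))
  mu <- sweep(2^mu_log2, 2, libsize / 1e6, `*`)
  if (any(mu <= 0)) abort("internal: nonpositive NB mean", class = "agesig_internal_error")
  counts <- matrix(
    rnbinom(length(mu), mu = mu, size = rep(1 / truth$dispersion, ncol(mu))),
    nrow = nrow(mu), dimnames = list(truth$gene_id, sample_ids)
  )
  list(
    counts = counts_to_tibble(counts),
    metadata = tibble(
      sample_id = sample_ids, species = species, sex = sex,
      tissue = tissue, age_months = ages
    )
  )
}

#' Plant pathway gene sets with known enrichment
#'
#' Draws `n_sets` gene sets over the truth-table universe. A fraction of the
#' sets is "enriched": a proportion `purity` of their members is drawn from
#' one trajectory class/direction (default linear-up), the rest uniformly.
#' Non-enriched sets are drawn uniformly. Each set is assigned to a level-2
#' system so the regulator-association stage can be exercised.
#'
#' @param truth A [sim_truth()] table.
#' @param n_sets Number of sets.
#' @param enriched_fraction Proportion of sets that are enriched.
#' @param set_size Length-2 inclusive bounds on set size.
#' @param enrich_class,enrich_direction Planted class (`"linear"` or
#'   `"logistic"`) and direction of the enriched sets.
#' @param purity Proportion of an enriched set drawn from the planted class.
#' @param n_systems Number of level-2 systems the sets are split across.
#' @param seed Integer seed.
#' @return A list: `sets` (named list of gene-id vectors), `systems`
#'   (tibble `pathway`, `system`), `set_truth` (tibble `pathway`, `enriched`).
#' @export
sim_gene_sets <- function(truth, n_sets = 30, enriched_fraction = 0.1,
                          set_size = c(10, 40),
                          enrich_class = "linear", enrich_direction = "up",
                          purity = 0.75, n_systems = 4, seed = 1L) {
  if (n_sets < 1) abort("`n_sets` must be >= 1", class = "agesig_config_error")
  if (max(set_size) > nrow(truth)) {
    abort("requested set size exceeds the gene universe",
          class = "agesig_config_error")
  }
  set.seed(seed)
  universe <- truth$gene_id
  pool <- truth$gene_id[truth$true_class == enrich_class &
                          truth$direction == enrich_direction]
  n_enriched <- round(n_sets * enriched_fraction)
  set_names <- sprintf("SET_%03d", seq_len(n_sets))
  enriched <- seq_len(n_sets) <= n_enriched
  sets <- lapply(seq_len(n_sets), function(i) {
    size <- sample(seq(set_size[1], set_size[2]), 1)
    if (enriched[i] && length(pool) > 0) {
      n_pl <- min(round(purity * size), length(pool))
      planted <- sample(pool, n_pl)
      filler <- sample(setdiff(universe, planted), size - n_pl)
      sample(c(planted, filler))
    } else {
      sample(universe, size)
    }
  })
  names(sets) <- set_names
  list(
    sets = sets,
    systems = tibble(
      pathway = set_names,
      system = sprintf("SYSTEM_%d", ((seq_len(n_sets) - 1) %% n_systems) + 1)
    ),
    set_truth = tibble(pathway = set_names, enriched = enriched)
  )
}

#' Plant a partially concordant cross-species ortholog map
#'
#' Builds a 1:1 map covering `coverage` of species-A genes. A mapped
#' age-related A gene is paired with a same-direction age-related B gene
#' with probability `concordance_prob`, otherwise (and for null A genes)
#' with a uniformly drawn unused B gene.
#'
#' @param truth_a,truth_b Truth tables of the two species.
#' @param concordance_prob Probability of a same-direction counterpart.
#' @param coverage Fraction of A genes that have an ortholog.
#' @param seed Integer seed.
#' @return A tibble (`gene_a`, `gene_b`); each gene appears at most once.
#' @export
sim_ortholog_map <- function(truth_a, truth_b, concordance_prob = 0.8,
                             coverage = 0.9, seed = 1L) {
  if (concordance_prob < 0 || concordance_prob > 1 ||
      coverage < 0 || coverage > 1) {
    abort("`concordance_prob` and `coverage` must be in [0, 1]",
          class = "agesig_config_error")
  }
  set.seed(seed)
  n_cov <- round(coverage * nrow(truth_a))
  if (n_cov == 0) return(tibble(gene_a = character(), gene_b = character()))
  a_genes <- sample(truth_a$gene_id, n_cov)
  # pair age-related query genes first so same-direction partner pools are
  # not consumed by the uniform background draws
  is_age <- truth_a$true_class[match(a_genes, truth_a$gene_id)] != "null"
  a_genes <- c(a_genes[is_age], a_genes[!is_age])
  avail <- rep(TRUE, nrow(truth_b))
  names(avail) <- truth_b$gene_id
  b_dir <- setNames(truth_b$direction, truth_b$gene_id)
  is_age_a <- setNames(truth_a$true_class != "null", truth_a$gene_id)
  dir_a <- setNames(truth_a$direction, truth_a$gene_id)

  pick <- function(pool) {
    pool <- pool[avail[pool]]
    if (length(pool) == 0) return(NA_character_)
    pool[sample.int(length(pool), 1)]
  }
  b_pick <- character(n_cov)
  for (i in seq_len(n_cov)) {
    g <- a_genes[i]
    choice <- NA_character_
    if (is_age_a[g] && runif(1) < concordance_prob) {
      choice <- pick(names(b_dir)[b_dir == dir_a[g]])
    }
    if (is.na(choice)) choice <- pick(names(avail))
    b_pick[i] <- choice
    avail[choice] <- FALSE
  }
  keep <- !is.na(b_pick)
  arrange(tibble(gene_a = a_genes[keep], gene_b = b_pick[keep]), .data$gene_a)
}

#' Plant a transcription-factor target network
#'
#' Appends `n_tfs` regulator genes to the truth table. A fraction of the
#' regulators is "correlated": their targets are drawn from a pool of planted
#' linear genes (default: all linear genes in `truth`) and the regulator's
#' own trajectory is a noisy copy of its targets' mean trajectory, so
#' regulator-target expression correlation is planted. Uncorrelated
#' regulators are null genes with uniformly drawn targets.
#'
#' @param truth A [sim_truth()] table.
#' @param n_tfs Number of regulators to add.
#' @param targets_per_tf Targets per regulator.
#' @param correlated_fraction Fraction of regulators that track their targets.
#' @param noise_sd SD of the log2-CPM noise added to the copied trajectory
#'   parameters.
#' @param target_pool Optional gene ids to draw correlated targets from;
#'   defaults to the linear genes of `truth`.
#' @param tf_prefix Prefix for regulator gene ids.
#' @param seed Integer seed.
#' @return A list: `truth` (input truth plus regulator rows), `interactions`
#'   (tibble `tf`, `target`), `whitelist` (regulator ids), `tf_truth`
#'   (tibble `tf`, `correlated`).
#' @export
sim_tf_network <- function(truth, n_tfs = 10, targets_per_tf = 10,
                           correlated_fraction = 0.5, noise_sd = 0.1,
                           target_pool = NULL, tf_prefix = "tf", seed = 1L) {
  if (n_tfs < 1) abort("`n_tfs` must be >= 1", class = "agesig_config_error")
  set.seed(seed)
  if (is.null(target_pool)) {
    target_pool <- truth$gene_id[truth$true_class == "linear"]
  }
  target_pool <- intersect(target_pool, truth$gene_id)
  n_corr <- round(correlated_fraction * n_tfs)
  tf_ids <- sprintf("%s_%03d", tf_prefix, seq_len(n_tfs))
  correlated <- seq_len(n_tfs) <= n_corr

  inter <- vector("list", n_tfs)
  tf_rows <- vector("list", n_tfs)
  truth_idx <- setNames(seq_len(nrow(truth)), truth$gene_id)
  for (i in seq_len(n_tfs)) {
    if (correlated[i] && length(target_pool) > 0) {
      tg <- sample(target_pool, min(targets_per_tf, length(target_pool)))
      tg_rows <- truth[truth_idx[tg], ]
      slope_i <- mean(tg_rows$slope, na.rm = TRUE)
      if (!is.finite(slope_i)) slope_i <- 0
      slope_i <- slope_i + rnorm(1, 0, noise_sd * 0.05)
      tf_rows[[i]] <- tibble(
        gene_id = tf_ids[i], true_class = "linear",
        direction = if (slope_i >= 0) "up" else "down",
        slope = slope_i, inflection_c = NA_real_, hill_b = NA_real_,
        amplitude = NA_real_,
        baseline_log2cpm = mean(tg_rows$baseline_log2cpm) + rnorm(1, 0, noise_sd),
        dispersion = rlnorm(1, log(0.05), 0.5)
      )
    } else {
      tg <- sample(truth$gene_id, min(targets_per_tf, nrow(truth)))
      tf_rows[[i]] <- tibble(
        gene_id = tf_ids[i], true_class = "null", direction = "none",
        slope = NA_real_, inflection_c = NA_real_, hill_b = NA_real_,
        amplitude = NA_real_,
        baseline_log2cpm = pmax(0.5, rnorm(1, 5, 1.5)),
        dispersion = rlnorm(1, log(0.05), 0.5)
      )
    }
    inter[[i]] <- tibble(tf = tf_ids[i], target = tg)
  }
  list(
    truth = bind_rows(truth, bind_rows(tf_rows)),
    interactions = bind_rows(inter),
    whitelist = tf_ids,
    tf_truth = tibble(tf = tf_ids, correlated = correlated)
  )
}

#' Simulate a complete two-species, two-tissue aging study
#'
#' Convenience generator that wires every planted artifact together:
#' per-species truth tables (the second species runs in rat mode with the
#' extra 9-month group), counts for each tissue drawn from the same species
#' truth (so planted age-related genes recur across tissues), planted
#' pathway sets, a partially concordant ortholog map, and a planted
#' regulator network whose correlated regulators target the first enriched
#' pathway's linear-up members.
#'
#' @param n_genes Genes per species.
#' @param n_per_group Samples per age group.
#' @param fractions Null/linear/logistic mixture.
#' @param tissues Tissue names simulated for both species.
#' @param n_sets Pathway sets per species.
#' @param concordance_prob,coverage Passed to [sim_ortholog_map()].
#' @param seed Integer master seed; all stage seeds derive from it.
#' @return An `aging_study` list: `counts` (named list of per-species count
#'   tibbles), `metadata`, `truth`, `gene_sets`, `systems`, `set_truth`,
#'   `orthologs`, `interactions`, `whitelist`, `tf_truth`, `designs`.
#' @examples
#' \donttest{
#' study <- sim_study(n_genes = 300, n_per_group = 4, seed = 1)
#' names(study$counts)
#' }
#' @export
sim_study <- function(n_genes = 1200, n_per_group = 8,
                      fractions = c(0.85, 0.10, 0.05),
                      tissues = c("gastrocnemius", "tibialis_anterior"),
                      n_sets = 30, concordance_prob = 0.7, coverage = 0.85,
                      seed = 1L) {
  species <- c("mouse", "rat")
  designs <- list(
    mouse = sim_design(n_genes = n_genes, n_per_group = n_per_group,
                       fractions = fractions),
    rat = sim_design(n_genes = n_genes, n_per_group = n_per_group,
                     fractions = fractions, rat_mode = TRUE)
  )
  prefixes <- c(mouse = "mm_", rat = "rn_")
  truth <- list(); nets <- list(); sets <- list(); set_truth <- list()
  counts <- list(); meta <- list(); systems <- NULL
  for (k in seq_along(species)) {
    sp <- species[k]
    tr <- sim_truth(designs[[sp]], seed = seed + 10 * k, prefix = prefixes[sp])
    gs <- sim_gene_sets(tr, n_sets = n_sets, enriched_fraction = 0.1,
                        set_size = c(15, 40), seed = seed + 10 * k + 1)
    enriched_sets <- gs$set_truth$pathway[gs$set_truth$enriched]
    pool <- if (length(enriched_sets) > 0) {
      intersect(gs$sets[[enriched_sets[1]]],
                tr$gene_id[tr$true_class == "linear" & tr$direction == "up"])
    } else NULL
    if (length(pool) < 5) pool <- NULL
    net <- sim_tf_network(tr, n_tfs = 8, targets_per_tf = 12,
                          correlated_fraction = 0.5, target_pool = pool,
                          tf_prefix = paste0(prefixes[sp], "tf"),
                          seed = seed + 10 * k + 2)
    truth[[sp]] <- net$truth
    nets[[sp]] <- net
    sets[[sp]] <- gs$sets
    set_truth[[sp]] <- mutate(gs$set_truth, species = sp)
    systems <- gs$systems  # same names/systems in both species
    cl <- list(); ml <- list()
    for (j in seq_along(tissues)) {
      sim <- sim_counts(net$truth, designs[[sp]],
                        seed = seed + 100 * k + j,
                        species = sp, tissue = tissues[j])
      cl[[j]] <- sim$counts
      ml[[j]] <- sim$metadata
    }
    wide <- cl[[1]]
    for (j in seq_along(tissues)[-1]) wide <- left_join(wide, cl[[j]], by = "gene_id")
    counts[[sp]] <- wide
    meta[[sp]] <- bind_rows(ml)
  }
  orthologs <- sim_ortholog_map(truth$mouse, truth$rat,
                                concordance_prob = concordance_prob,
                                coverage = coverage, seed = seed + 7)
  structure(
    list(
      counts = counts,
      metadata = bind_rows(meta),
      truth = truth,
      gene_sets = sets,
      systems = systems,
      set_truth = bind_rows(set_truth),
      orthologs = orthologs,
      interactions = list(mouse = nets$mouse$interactions,
                          rat = nets$rat$interactions),
      whitelist = list(mouse = nets$mouse$whitelist, rat = nets$rat$whitelist),
      tf_truth = list(mouse = nets$mouse$tf_truth, rat = nets$rat$tf_truth),
      designs = designs,
      seed = seed
    ),
    class = "aging_study"
  )
}

counts_to_tibble <- function(m) {
  out <- as_tibble(m, rownames = "gene_id")
  out
}
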