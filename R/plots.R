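#' Bar chart of age-related gene counts per class and stratum
#'
#' The tabular analog of the study-design summary: one facet per species x
#' tissue, bars split by trajectory class and coloured by direction.
#'
#' @param x An `aging_pipeline`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_class_counts <- function(x, ...) {
  stopifnot(inherits(x, "aging_pipeline"))
  df <- x$class_counts %>%
    mutate(direction = class_direction(.data$label),
           label = factor(.data$label, levels = AGE_CLASSES))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$n_genes,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(species ~ tissue) +
    ggplot2::scale_fill_manual(values = c(up = "#c0392b", down = "#27ae60")) +
    ggplot2::labs(x = NULL, y = "age-related genes", fill = "direction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Circle-summary heatmap of retained pathways
#'
#' Circles per pathway and contrast age, sized by the enriched-gene bin
#' (small 0-5, medium 6-15, large >15) and coloured by the mean fold change
#' versus the reference age, saturating at the recorded fold cap.
#'
#' @param x An `aging_pipeline`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_circle_summary <- function(x, ...) {
  stopifnot(inherits(x, "aging_pipeline"))
  df <- x$circle_summary
  if (nrow(df) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "no retained pathways"))
  }
  cap <- df$fold_cap[1]
  df <- mutate(df,
               bin = factor(.data$bin, levels = c("small", "medium", "large")),
               fc = pmax(pmin(.data$mean_log2_fc, log2(cap)), -log2(cap)))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$contrast_age),
                                   y = .data$pathway,
                                   size = .data$bin, colour = .data$fc)) +
    ggplot2::geom_point() +
    ggplot2::facet_grid(class ~ species + tissue) +
    ggplot2::scale_size_manual(values = c(small = 1.5, medium = 3, large = 5)) +
    ggplot2::scale_colour_gradient2(low = "#2166ac", mid = "grey85",
                                    high = "#b2182b", midpoint = 0,
                                    limits = c(-log2(cap), log2(cap))) +
    ggplot2::labs(x = "age (months)", y = NULL,
                  colour = "mean log2 FC", size = "genes") +
    ggplot2::theme_minimal()
}

#' Plot one gene's expression trajectory with its fitted models
#'
#' @param expr A [log2_cpm()] tibble.
#' @param metadata Per-sample metadata.
#' @param gene Gene id to plot.
#' @param fit Optional one-row [fit_trajectory()] result for overlays.
#' @return A ggplot object.
#' @export
plot_gene_trajectory <- function(expr, metadata, gene, fit = NULL) {
  m <- expr_matrix(expr)
  metadata <- filter(metadata, .data$sample_id %in% colnames(m))
  df <- tibble(age = metadata$age_months,
               log2_cpm = m[gene, metadata$sample_id])
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$log2_cpm)) +
    ggplot2::geom_jitter(width = 0.3, alpha = 0.6) +
    ggplot2::labs(title = gene, x = "age (months)", y = "log2 CPM") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    tt <- seq(min(df$age), max(df$age), length.out = 120)
    lines <- bind_rows(
      tibble(age = tt, value = mean(df$log2_cpm), model = "null"),
      tibble(age = tt,
             value = fit$linear_intercept + fit$linear_slope * tt,
             model = "linear"),
      if (isTRUE(fit$logistic_ok)) {
        tibble(age = tt,
               value = logistic4(tt, fit$logistic_A, fit$logistic_D,
                                 fit$logistic_c, fit$logistic_b),
               model = "logistic")
      }
    )
    g <- g + ggplot2::geom_line(
      data = lines,
      ggplot2::aes(x = .data$age, y = .data$value, colour = .data$model)
    )
  }
  g
}

#' @method autoplot aging_pipeline
#' @export
autoplot.aging_pipeline <- function(object, type = c("classes", "circles"),
                                    ...) {
  type <- match.arg(type)
  switch(type,
         classes = plot_class_counts(object, ...),
         circles = plot_circle_summary(object, ...))
}

#' @method autoplot trajectory_result
#' @export
autoplot.trajectory_result <- function(object, ...) {
  df <- mutate(object$counts,
               direction = class_direction(.data$label),
               label = factor(.data$label, levels = AGE_CLASSES))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$n_genes,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(up = "#c0392b", down = "#27ae60")) +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal()
}
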