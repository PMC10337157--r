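#' Upper-tail hypergeometric probability of direction concordance
#'
#' Probability of observing `k_concordant` or more same-direction pairs:
#' `p = sum_{i=k}^{n} C(K, i) C(N-K, n-i) / C(N, n)`, evaluated in
#' log-gamma arithmetic so values of order 1e-15 are exact to at least six
#' significant digits.
#'
#' @param n_query Query-species age-related genes of the direction that have
#'   an ortholog.
#' @param k_concordant How many of those have a same-direction age-related
#'   ortholog.
#' @param K_target Mapped query genes whose ortholog is age-related in the
#'   same direction in the other species.
#' @param N_total All query genes that have an ortholog.
#' @return The upper-tail probability (1 when `k_concordant <= 0`).
#' @examples
#' concordance_test(82, 20, 369, 14838)  # ~7.5e-15
#' @export
concordance_test <- function(n_query, k_concordant, K_target, N_total) {
  if (any(c(n_query, k_concordant, K_target, N_total) < 0) ||
      k_concordant > min(n_query, K_target) || n_query > N_total ||
      K_target > N_total) {
    abort("invalid hypergeometric quadruple", class = "agesig_input_error")
  }
  if (k_concordant <= 0) return(1)
  i <- seq(k_concordant, min(n_query, K_target))
  lt <- lchoose(K_target, i) + lchoose(N_total - K_target, n_query - i) -
    lchoose(N_total, n_query)
  # sum in log space from the largest term for accuracy in the far tail
  mx <- max(lt)
  min(1, exp(mx) * sum(exp(lt - mx)))
}

#' Build cross-species direction-concordance count quadruples
#'
#' For each tissue shared by the two species and each direction, counts the
#' hypergeometric inputs in both mapping orientations (A to B and B to A; a
#' non-bijective map makes them differ) and computes the upper-tail
#' probability with [concordance_test()]. Age-related genes are pooled over
#' linear and logistic classes by direction. `N_total` counts every query
#' gene with an ortholog, whether or not age-related.
#'
#' @param classes_a,classes_b Trajectory-class tibbles (`gene_id`, `tissue`,
#'   `label`) covering the full expression universe of species A and B.
#' @param ortholog_map Tibble (`gene_a`, `gene_b`); first candidate per
#'   source gene is kept per orientation.
#' @return Tibble: `orientation`, `tissue`, `direction`, `n_query`,
#'   `k_concordant`, `K_target`, `N_total`, `p`, `degenerate`.
#' @export
ortholog_concordance <- function(classes_a, classes_b, ortholog_map) {
  tissues <- intersect(unique(classes_a$tissue), unique(classes_b$tissue))
  out <- list()
  for (orient in c("A_to_B", "B_to_A")) {
    if (orient == "A_to_B") {
      qc <- classes_a; tc <- classes_b
      map <- ortholog_map[!duplicated(ortholog_map$gene_a), ]
      partner <- setNames(map$gene_b, map$gene_a)
    } else {
      qc <- classes_b; tc <- classes_a
      map <- ortholog_map[!duplicated(ortholog_map$gene_b), ]
      partner <- setNames(map$gene_a, map$gene_b)
    }
    q_universe <- unique(qc$gene_id)
    mapped <- intersect(q_universe, names(partner))
    N <- length(mapped)
    for (ti in tissues) {
      for (dir in c("up", "down")) {
        if (N == 0) {
          out[[length(out) + 1]] <- tibble(
            orientation = orient, tissue = ti, direction = dir,
            n_query = 0L, k_concordant = 0L, K_target = 0L, N_total = 0L,
            p = NA_real_, degenerate = TRUE
          )
          next
        }
        q_dir <- qc$gene_id[qc$tissue == ti &
                              class_direction(qc$label) == dir]
        t_dir <- tc$gene_id[tc$tissue == ti &
                              class_direction(tc$label) == dir]
        q_set <- intersect(q_dir, mapped)
        hits_target <- mapped[partner[mapped] %in% t_dir]
        k <- length(intersect(q_set, hits_target))
        out[[length(out) + 1]] <- tibble(
          orientation = orient, tissue = ti, direction = dir,
          n_query = length(q_set), k_concordant = k,
          K_target = length(hits_target), N_total = N,
          p = concordance_test(length(q_set), k, length(hits_target), N),
          degenerate = FALSE
        )
      }
    }
  }
  bind_rows(out)
}
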