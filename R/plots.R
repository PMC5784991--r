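# ggplot2 views of the main result types.

#' Plot a hybrid census
#'
#' Bar chart of hybrid counts by genotype class and cross type of the family
#' of birth, showing the asymmetry between aAF and fFA hybrids.
#'
#' @param object A [hybrid_census()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hybrid_census <- function(object, ...) {
  ggplot2::ggplot(
    object$origins,
    ggplot2::aes(x = .data$genotype, y = .data$n, fill = .data$cross_type)
  ) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(
      x = "hybrid genotype class", y = "individuals",
      fill = "cross type of family of birth",
      title = "Hybrid census by origin"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a simulated mating experiment summary
#'
#' Sterile-cocoon percentages and cocoon rates per design arm.
#'
#' @param object A [simulate_experiment()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mating_sim <- function(object, ...) {
  long <- object$summary |>
    select("arm", "cocoons_per_worm_week", "pct_sterile") |>
    pivot_longer(-"arm", names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$arm, y = .data$value)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Simulated reproduction by arm") +
    ggplot2::theme_minimal()
}

#' Histogram of pairwise p-distances
#'
#' Visualises the gap between within-cluster and between-cluster distances
#' that threshold clustering exploits.
#'
#' @param seqs An aligned sequence set, or a precomputed distance matrix from
#'   [p_distance_matrix()].
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_distance_histogram <- function(seqs, bins = 30) {
  d <- if (is.matrix(seqs)) seqs else p_distance_matrix(seqs)
  vals <- d[upper.tri(d)]
  ggplot2::ggplot(tibble(p_distance = vals),
                  ggplot2::aes(x = .data$p_distance)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::labs(x = "pairwise p-distance", y = "pairs") +
    ggplot2::theme_minimal()
}
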