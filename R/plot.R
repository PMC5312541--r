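#' Plot directional-bias frequencies
#'
#' Line plot of type I and type II bias frequencies against the simulated
#' trait-signal level, faceted by degradation level (columns) and tree
#' size (rows), for one signal index and one treatment family at a time.
#'
#' @param object A `bias_table` from [bias_frequencies()].
#' @param index `"K"` or `"lambda"`; defaults to the first index present.
#' @param treatment Treatment family to show; defaults to the first
#'   non-true treatment present.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' cfg <- experiment_config(
#'   tree_sizes = 50, n_trees = 2, lambda_grid = c(0.2, 0.8),
#'   collapse_fractions = 0.4, collapse_strategies = "shallow",
#'   fix_fractions = 0.15, n_perm = 49, seed = 1
#' )
#' run <- run_experiment(cfg)
#' ggplot2::autoplot(run$bias, index = "K", treatment = "polytomic_shallow")
#' @method autoplot bias_table
#' @export
autoplot.bias_table <- function(object, index = NULL, treatment = NULL, ...) {
  index <- index %||% object$index[1]
  treatment <- treatment %||% object$treatment[1]
  dat <- object |>
    dplyr::filter(.data$index == !!index, .data$treatment == !!treatment) |>
    tidyr::pivot_longer(c("freq_typeI", "freq_typeII"),
      names_to = "bias", names_prefix = "freq_", values_to = "frequency"
    )
  ggplot2::ggplot(
    dat,
    ggplot2::aes(
      x = .data$lambda_sim, y = .data$frequency,
      colour = .data$bias, linetype = .data$bias
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$n_tips),
      cols = ggplot2::vars(.data$level),
      labeller = ggplot2::label_both
    ) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%g%%", 100 * v)) +
    ggplot2::labs(
      x = "simulated signal (lambda rescaling)",
      y = "bias frequency",
      title = sprintf("Directional biases: %s, %s", index, treatment)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Compare branch-length variability of true and degraded trees
#'
#' Histograms of branch-length standard deviations for a set of true
#' chronograms and one set of degraded counterparts, the visual signature
#' of BLADJ-style calibration.
#'
#' @param true_trees,degraded_trees Lists of chronograms of equal length.
#' @param labels Length-2 character vector naming the two sets.
#' @return A ggplot object.
#' @export
plot_branch_length_sd <- function(true_trees, degraded_trees,
                                  labels = c("true", "degraded")) {
  dat <- dplyr::bind_rows(
    tibble::tibble(
      set = labels[1],
      sd = vapply(true_trees, branch_length_sd, 0)
    ),
    tibble::tibble(
      set = labels[2],
      sd = vapply(degraded_trees, branch_length_sd, 0)
    )
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sd, fill = .data$set)) +
    ggplot2::geom_histogram(
      position = "identity", alpha = 0.5, bins = 30
    ) +
    ggplot2::labs(x = "branch-length standard deviation", y = "trees") +
    ggplot2::theme_minimal()
}
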