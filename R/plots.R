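# ggplot2 views of the main result types.

#' Density of pairwise distances with candidate thresholds
#'
#' Plots the Gaussian kernel density of all pairwise distances and marks
#' the local minima that [local_minima_thresholds()] would propose; a
#' clear dip between the intra- and interspecific modes is the barcoding
#' gap.
#'
#' @param distances Numeric vector of pairwise distances.
#' @param bw,n_points,cut Density settings as in
#'   [local_minima_thresholds()].
#' @return A ggplot object.
#' @export
plot_distance_density <- function(distances, bw = "nrd0", n_points = 512,
                                  cut = 3) {
  dens <- stats::density(distances[!is.na(distances)], bw = bw,
                         kernel = "gaussian", n = n_points, cut = cut)
  minima <- local_minima_thresholds(distances, bw = bw,
                                    n_points = n_points, cut = cut)
  df <- tibble(distance = dens$x, density = dens$y)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$distance,
                                        y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pairwise distance (substitutions/site)",
                  y = "density")
  if (length(minima) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = minima, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' @describeIn thresh_opt Plot the cumulative identification error across
#'   the threshold grid, with the selected optimum marked.
#' @param object A `coigap_threshopt` object.
#' @param ... Ignored.
#' @method autoplot coigap_threshopt
#' @export
autoplot.coigap_threshopt <- function(object, ...) {
  ggplot2::ggplot(object$scan,
                  ggplot2::aes(x = .data$threshold,
                               y = .data$cumulative_error)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$optimum, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "threshold (substitutions/site)",
                  y = "false positives + false negatives")
}

#' Histogram of maximum intraspecific distances by order
#'
#' @param species_stats The `species_stats` tibble of
#'   [run_species_analysis()].
#' @param bin_width Class interval (default 0.01).
#' @return A ggplot object faceted by order.
#' @export
plot_max_intra_histogram <- function(species_stats, bin_width = 0.01) {
  assert_records(species_stats, need = c("order_name", "max_intra"),
                 arg = "species_stats")
  ggplot2::ggplot(species_stats, ggplot2::aes(x = .data$max_intra)) +
    ggplot2::geom_histogram(binwidth = bin_width, boundary = 0,
                            closed = "left", fill = "steelblue",
                            colour = "white") +
    ggplot2::facet_wrap(ggplot2::vars(.data$order_name)) +
    ggplot2::labs(x = "maximum intraspecific distance", y = "species")
}

#' Species-outcome counts per delimitation method
#'
#' Stacked bars of the MATCH/SPLIT/MERGE/MIXTURE totals of each method.
#'
#' @param method_summary The `method_summary` tibble of
#'   [run_genus_analysis()].
#' @return A ggplot object.
#' @export
plot_outcome_counts <- function(method_summary) {
  assert_records(method_summary,
                 need = c("method", "MATCH", "SPLIT", "MERGE", "MIXTURE"),
                 arg = "method_summary")
  long <- tidyr::pivot_longer(method_summary,
                              cols = c("MATCH", "SPLIT", "MERGE", "MIXTURE"),
                              names_to = "outcome", values_to = "n")
  long$outcome <- factor(long$outcome,
                         levels = c("MATCH", "SPLIT", "MERGE", "MIXTURE"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$n,
                                     fill = .data$outcome)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "species", fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
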