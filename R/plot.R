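# ggplot2 helpers for tracks, universes and assessment results.

#' Plot the three signal tracks of a collection
#'
#' @param tracks A `signal_tracks` object.
#' @param chrom Chromosome to show (default: first).
#' @param from,to Optional coordinate window.
#' @return A ggplot object (step lines per track).
#' @export
plot_tracks <- function(tracks, chrom = names(tracks$chrom_sizes)[1],
                        from = NULL, to = NULL) {
  d <- tracks$runs[tracks$runs$chrom == chrom, , drop = FALSE]
  if (!is.null(from)) d <- d[d$end > from, , drop = FALSE]
  if (!is.null(to)) d <- d[d$start < to, , drop = FALSE]
  long <- tidyr::pivot_longer(d, c("starts", "core", "ends"),
                              names_to = "track", values_to = "count")
  long$track <- factor(long$track, levels = c("starts", "core", "ends"))
  ggplot2::ggplot(long) +
    ggplot2::geom_step(ggplot2::aes(x = .data$start, y = .data$count)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$track)) +
    ggplot2::labs(x = sprintf("%s position (bp)", chrom), y = "sets") +
    ggplot2::theme_minimal()
}

#' @method autoplot universe
#' @export
autoplot.universe <- function(object, chrom = NULL, from = NULL, to = NULL, ...) {
  d <- as_tibble(object)
  if (!is.null(chrom)) d <- d[d$chrom == chrom, , drop = FALSE]
  if (!is.null(from)) d <- d[d$end > from, , drop = FALSE]
  if (!is.null(to)) d <- d[d$start < to, , drop = FALSE]
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$chrom, yend = .data$chrom),
                          linewidth = 2, colour = "grey70") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$core_start,
                                       xend = pmax(.data$core_end, .data$core_start + 0.5),
                                       y = .data$chrom, yend = .data$chrom),
                          linewidth = 4, colour = "grey20") +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = sprintf("%s universe (outer span grey, core black)",
                                  attr(object, "method") %||% "")) +
    ggplot2::theme_minimal()
}

#' @method autoplot universe_fit
#' @export
autoplot.universe_fit <- function(object, ...) {
  cols <- intersect(c("precision", "recall", "f10", "rbd"),
                    names(object$per_set))
  long <- tidyr::pivot_longer(object$per_set[, c("set", cols)], -"set",
                              names_to = "metric", values_to = "score")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$set, y = .data$score)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
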