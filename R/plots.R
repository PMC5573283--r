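#' Plot methods
#'
#' `autoplot()` methods give a quick look at each result type: stability
#' and copy-number traces for trajectories and ensembles, the objective
#' surface for grid fits, data-vs-model overlays for densitometry fits,
#' and bar charts for copy-number and multimer distributions.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name plasmidrift-autoplot
NULL

trace_plot <- function(df, has_sd) {
  long <- tidyr::pivot_longer(
    df[intersect(names(df), c("generation", "S", "PCN"))],
    cols = c("S", "PCN"), names_to = "observable", values_to = "value"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$generation, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~observable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "generation", y = NULL)
  if (has_sd) {
    band <- dplyr::bind_rows(
      tibble::tibble(generation = df$generation, observable = "S",
                     lo = df$S - df$S_sd, hi = df$S + df$S_sd),
      tibble::tibble(generation = df$generation, observable = "PCN",
                     lo = df$PCN - df$PCN_sd, hi = df$PCN + df$PCN_sd)
    )
    p <- p + ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$generation, ymin = .data$lo, ymax = .data$hi),
      inherit.aes = FALSE, alpha = 0.2
    )
  }
  p
}

#' @rdname plasmidrift-autoplot
#' @export
autoplot.plasmid_trajectory <- function(object, ...) {
  trace_plot(object, has_sd = FALSE)
}

#' @rdname plasmidrift-autoplot
#' @export
autoplot.plasmid_ensemble <- function(object, ...) {
  trace_plot(object, has_sd = TRUE)
}

#' @rdname plasmidrift-autoplot
#' @export
autoplot.cn_dist <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$n, y = .data$abundance)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::labs(x = "plasmid units per cell", y = "abundance")
}

#' @rdname plasmidrift-autoplot
#' @export
autoplot.stability_fit <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$value, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$estimate, linetype = 2) +
    ggplot2::labs(x = object$parameter, y = "sum of squared errors")
}

#' @rdname plasmidrift-autoplot
#' @export
autoplot.multimer_fit <- function(object, ...) {
  df <- object$profile
  df$fitted <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$intensity), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red",
                       linetype = 2) +
    ggplot2::labs(x = "size", y = "intensity")
}

#' @rdname plasmidrift-autoplot
#' @export
autoplot.multimer_distribution <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = factor(.data$k), y = .data$rho)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "multimer rank", y = "fraction")
}
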