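#' Plot the summary series of a run
#'
#' Two stacked panels: the mean field \eqn{\bar u(t)} and
#' \eqn{\log \sigma(t)} with the fitted growth line (red) and the plateau
#' level (black); their intersection is the crossover time.
#'
#' @param object A `camp_trajectory`.
#' @param n_head,n_tail Analysis windows, see [fit_growth_line()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot camp_trajectory
#' @export
autoplot.camp_trajectory <- function(object, n_head = 300L, n_tail = 3000L,
                                     ...) {
  s <- object$series
  n_tail <- min(n_tail, nrow(s) %/% 2L)
  an <- analyze_trajectory(object, n_head = n_head, n_tail = n_tail)
  long <- tidyr::pivot_longer(
    dplyr::mutate(s, log_sigma = log(pmax(.data$sigma, .Machine$double.xmin))),
    c("ubar", "log_sigma"),
    names_to = "stat", values_to = "value"
  )
  long$stat <- factor(long$stat,
    levels = c("ubar", "log_sigma"),
    labels = c("mean field", "log sigma")
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~stat, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL)
  if (is.finite(an$slope) && is.finite(an$plateau)) {
    guides <- tibble::tibble(
      stat = factor("log sigma", levels = levels(long$stat)),
      slope = c(an$slope, 0),
      intercept = c(an$intercept, an$plateau),
      which = c("growth fit", "plateau")
    )
    p <- p + ggplot2::geom_abline(
      data = guides,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
        color = .data$which
      ),
      linetype = "dashed"
    ) +
      ggplot2::scale_color_manual(
        values = c("growth fit" = "red", "plateau" = "black"), name = NULL
      )
  }
  p
}

#' Plot a kymograph
#'
#' Space-time raster of \eqn{\sqrt{u}} along the recorded lattice row;
#' travelling fronts appear as bright diagonal stripes.
#'
#' @param object A [kymograph()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot camp_kymograph
#' @export
autoplot.camp_kymograph <- function(object, ...) {
  iters <- attr(object, "iterations")
  df <- tidyr::expand_grid(t = seq_along(iters), x = seq_len(ncol(object)))
  df$value <- object[cbind(df$t, df$x)]
  df$iteration <- iters[df$t]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$iteration,
    fill = .data$value
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "sqrt(u)") +
    ggplot2::labs(x = "lattice column", y = "iteration")
}

#' Plot one field snapshot
#'
#' @param u Field matrix (e.g. `trajectory$snapshots$u[[k]]`).
#' @param sqrt_scale Show \eqn{\sqrt{\max(u, 0)}} instead of raw `u`
#'   (matches the kymograph scaling)?
#' @return A ggplot object.
#' @export
plot_snapshot <- function(u, sqrt_scale = TRUE) {
  stopifnot(is.matrix(u))
  val <- if (sqrt_scale) sqrt(pmax(u, 0)) else u
  df <- tidyr::expand_grid(row = seq_len(nrow(u)), col = seq_len(ncol(u)))
  df$value <- val[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = if (sqrt_scale) "sqrt(u)" else "u") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Heatmap of a survey table
#'
#' @param survey A [run_survey()] result.
#' @param value Column to show (default `"S"`).
#' @return A ggplot object.
#' @export
plot_survey <- function(survey, value = "S") {
  stopifnot(is.data.frame(survey), value %in% names(survey))
  agg <- dplyr::summarise(
    dplyr::group_by(survey, .data$phi1, .data$phi2),
    value = mean(.data[[value]], na.rm = TRUE), .groups = "drop"
  )
  ggplot2::ggplot(agg, ggplot2::aes(
    factor(.data$phi2), factor(.data$phi1),
    fill = .data$value
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = value) +
    ggplot2::labs(x = "phi2 (reactive fraction)", y = "phi1 (density)")
}
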