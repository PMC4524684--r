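# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   facet_wrap labs theme_minimal
NULL

#' Scatter of two cleft measures along one or more trajectories
#'
#' The standard cooperativity view: e.g. d(AB) against d(BA), or cleft
#' angle ABC against BCD. Anti-symmetric cooperative motion runs along the
#' anti-diagonal, symmetric motion along the diagonal.
#'
#' @param measures tidy measure tibble (`frame`, `measure`, `value`),
#'   optionally with a `run` column to colour by.
#' @param m1,m2 measure names for the x and y axes.
#' @return a ggplot object.
#' @export
plot_measure_pair <- function(measures, m1 = "d_AB", m2 = "d_BA") {
  wide <- tidyr::pivot_wider(
    dplyr::filter(measures, .data$measure %in% c(m1, m2)),
    names_from = "measure", values_from = "value")
  p <- if ("run" %in% names(wide)) {
    ggplot(wide, aes(x = .data[[m1]], y = .data[[m2]], colour = .data$run))
  } else {
    ggplot(wide, aes(x = .data[[m1]], y = .data[[m2]]))
  }
  p + geom_point(size = 0.8) + theme_minimal() +
    labs(x = m1, y = m2)
}

#' Measure traces along a trajectory
#'
#' @param measures tidy measure tibble (`frame`, `measure`, `value`).
#' @return a ggplot object faceted by measure.
#' @export
plot_measure_series <- function(measures) {
  ggplot(measures, aes(x = .data$frame, y = .data$value)) +
    geom_line() + facet_wrap(~measure, scales = "free_y") +
    theme_minimal() + labs(x = "frame", y = NULL)
}

#' @export
autoplot.traj_pca <- function(object, n = 10, ...) {
  td <- utils::head(tidy(object), n)
  ggplot(td, aes(x = factor(.data$pc), y = .data$var_frac)) +
    geom_col() + theme_minimal() +
    labs(x = "principal component", y = "variance fraction")
}

#' @export
autoplot.enm_modes <- function(object, n = 30, ...) {
  df <- tibble(mode = seq_along(object$values),
               eigenvalue = object$values)[seq_len(min(n, length(object$values))), ]
  ggplot(df, aes(x = .data$mode, y = .data$eigenvalue)) +
    geom_point() + theme_minimal() +
    labs(x = "mode number", y = "eigenvalue (spring units)")
}

#' @export
autoplot.correlation_series <- function(object, ...) {
  ggplot(object$windows, aes(x = .data$start, y = .data$r)) +
    geom_line() + geom_point(size = 0.8) + theme_minimal() +
    labs(x = "window start (frame)", y = "Pearson R")
}

#' @export
autoplot.geosim_trajectory <- function(object, ...) {
  ggplot(object$stats, aes(x = .data$step, y = .data$violation)) +
    geom_line() + theme_minimal() +
    labs(x = "step", y = "max constraint violation (A)")
}

#' @export
autoplot.reference_comparison <- function(object, ...) {
  ggplot(object$series, aes(x = .data$frame, y = .data$rmsd)) +
    geom_line() + geom_point(size = 0.8) + theme_minimal() +
    labs(x = "frame", y = "Calpha RMSD (A)")
}
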