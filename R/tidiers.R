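#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a refinement batch: one row per run
#' @param x a `refine_batch`.
#' @param ... unused.
#' @method tidy refine_batch
#' @export
tidy.refine_batch <- function(x, ...) x$report

#' One-row summary of a refinement batch
#' @param x a `refine_batch`.
#' @param ... unused.
#' @method glance refine_batch
#' @export
glance.refine_batch <- function(x, ...) {
  tibble::tibble(n_runs = nrow(x$report), n_accepted = length(x$models),
                 n_conformers = x$n_conformers, n_restraints = x$n_restraints,
                 best_max_violation = min(x$report$max_violation),
                 seed = x$seed)
}

#' Tidy an ensemble-size scan: one row per N
#' @param x an `ensemble_scan`.
#' @param ... unused.
#' @method tidy ensemble_scan
#' @export
tidy.ensemble_scan <- function(x, ...) x$per_n

#' One-row summary of an ensemble-size scan
#' @param x an `ensemble_scan`.
#' @param ... unused.
#' @method glance ensemble_scan
#' @export
glance.ensemble_scan <- function(x, ...) {
  tibble::tibble(chosen_n = x$chosen_n, n_restraints = x$n_restraints,
                 n_scanned = nrow(x$per_n))
}

#' Violation-versus-ensemble-size curve
#'
#' Average restraint violation (left axis of the published scan figure) and
#' satisfied-restraint count against the number of conformers.
#'
#' @param object an `ensemble_scan`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ensemble_scan
#' @export
autoplot.ensemble_scan <- function(object, ...) {
  df <- object$per_n
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_conformers)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$average_violation),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$average_violation),
                        colour = "steelblue") +
    ggplot2::geom_col(ggplot2::aes(y = .data$n_satisfied *
                                     max(df$average_violation, 0.1) /
                                     max(df$n_satisfied)),
                      alpha = 0.25, fill = "darkorange", width = 0.5) +
    ggplot2::scale_x_continuous(breaks = df$n_conformers) +
    ggplot2::labs(x = "conformers in ensemble (N)",
                  y = "average restraint violation (Å)",
                  subtitle = "bars: satisfied restraints (rescaled)") +
    ggplot2::theme_minimal()
}

#' Spherical-projection scatter of conformer positions
#'
#' Polar angle against azimuth of the mobile subunit's center of mass,
#' coloured by cluster when [cluster_models()] has been applied.
#'
#' @param object a `spherical_projection` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot spherical_projection
#' @export
autoplot.spherical_projection <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$phi, y = .data$theta))
  if ("cluster" %in% names(object)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data$cluster)),
                                 alpha = 0.7) +
      ggplot2::labs(colour = "cluster")
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7)
  }
  p + ggplot2::scale_x_continuous(limits = c(-180, 180),
                                  breaks = seq(-180, 180, 90)) +
    ggplot2::scale_y_continuous(limits = c(0, 180), breaks = seq(0, 180, 45)) +
    ggplot2::labs(x = "azimuth φ (deg)", y = "polar angle θ (deg)") +
    ggplot2::theme_minimal()
}

#' Maximum-intensity projection of a probability map
#'
#' Projects the 3-D occupancy grid along z and draws the map at a
#' fraction-of-maximum threshold contour.
#'
#' @param object a `probability_map`.
#' @param threshold fraction of the maximum to contour at (default 0.2).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot probability_map
#' @export
autoplot.probability_map <- function(object, threshold = 0.2, ...) {
  g <- apply(object$grid, c(1, 2), max)
  df <- expand.grid(
    x = object$origin[1] + (seq_len(nrow(g)) - 1) * object$spacing,
    y = object$origin[2] + (seq_len(ncol(g)) - 1) * object$spacing)
  df$density <- as.numeric(g)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$density)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$density),
                          breaks = threshold, colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (Å)", y = "y (Å)",
                  fill = "occupancy") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
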