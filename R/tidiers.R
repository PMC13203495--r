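# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @method tidy fsi_run
#' @export
tidy.fsi_run <- function(x, ...) x$metrics

#' @method glance fsi_run
#' @export
glance.fsi_run <- function(x, ...) {
  inner <- x$metrics[x$metrics$level == "inner", ]
  outer <- x$metrics[x$metrics$level == "outer", ]
  tibble::tibble(
    scenario = x$scenario,
    dt = x$dt,
    n_steps = x$n_steps,
    simulated_s = x$n_steps * x$dt,
    peak_vm_pa = max(x$stress$vm_max),
    peak_brain_skull_mm = 1000 * max(x$displacement$brain_skull_m),
    inner_max_dev = max(abs(1 - inner$normalized)),
    outer_max_dev = max(abs(1 - outer$normalized)),
    inner_mean_abs_dev = mean(abs(1 - inner$normalized)),
    outer_mean_abs_dev = mean(abs(1 - outer$normalized)),
    max_penetration_m = max(x$diagnostics$max_penetration_m),
    elapsed_s = x$elapsed_s)
}

#' @method tidy fsi_comparison
#' @export
tidy.fsi_comparison <- function(x, ...) x$summary

#' @method glance fsi_comparison
#' @export
glance.fsi_comparison <- function(x, ...) {
  tibble::tibble(
    vm_attenuation_percent =
      x$summary$attenuation_percent[x$summary$quantity ==
                                    "peak_brain_von_mises_pa"],
    displacement_attenuation_percent =
      x$summary$attenuation_percent[x$summary$quantity ==
                                    "peak_brain_skull_displacement_m"],
    nested_peak_vm_pa = x$summary$nested[1],
    no_fluids_peak_vm_pa = x$summary$no_fluids[1])
}

#' @method glance kin_trace
#' @export
glance.kin_trace <- function(x, ...) {
  r <- attr(x, "realized")
  if (is.null(r)) {
    fs <- 1 / diff(x$time_s[1:2])
    r <- list(peak_angular_velocity = max(abs(x$roll_rate_rad_s)),
              peak_angular_acceleration = max(abs(x$roll_accel_rad_s2)),
              angular_displacement_range = diff(range(x$roll_rad)),
              dominant_frequency = dominant_frequency(x$roll_rad, fs))
  }
  tibble::tibble(
    peak_angular_velocity = r$peak_angular_velocity,
    peak_angular_acceleration = r$peak_angular_acceleration,
    angular_displacement_range = r$angular_displacement_range,
    dominant_frequency = r$dominant_frequency,
    duration_s = max(x$time_s),
    n = nrow(x))
}

#' Plot normalized separation series of a run
#'
#' Normalized landmark-to-surface separations over time, faceted by
#' protection level (outer: fetus-uterus; inner: brain-skull). The dashed
#' line marks the baseline (1): hierarchical cushioning shows as large outer
#' excursions with the inner level pinned near 1.
#'
#' @param object An `fsi_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fsi_run
#' @export
autoplot.fsi_run <- function(object, ...) {
  ggplot2::ggplot(object$metrics,
                  ggplot2::aes(.data$time, .data$normalized,
                               colour = .data$landmark)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~level, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "separation / baseline",
                  title = sprintf("Cushioning distances (%s scenario)",
                                  object$scenario))
}

#' Plot the protected versus unprotected brain stress histories
#'
#' @param object An `fsi_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fsi_comparison
#' @export
autoplot.fsi_comparison <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$nested$stress, scenario = "nested"),
    dplyr::mutate(object$no_fluids$stress, scenario = "no_fluids"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$vm_max / 1000,
                                   colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "peak brain von Mises stress (kPa)",
                  title = "Protected vs unprotected brain loading")
}

#' Plot a seizure kinematics trace
#'
#' @param object A `kin_trace`.
#' @param ... Unused.
#' @return A ggplot object with roll angle and roll rate panels.
#' @method autoplot kin_trace
#' @export
autoplot.kin_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object[, c("time_s", "roll_rad", "roll_rate_rad_s")],
    -"time_s", names_to = "signal")
  df$signal <- factor(df$signal, c("roll_rad", "roll_rate_rad_s"),
                      c("roll angle (rad)", "roll rate (rad/s)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}
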