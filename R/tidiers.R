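# broom-style tidiers and ggplot2 autoplot methods for result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation result
#'
#' Returns the moment-rotation curve as a tibble.
#'
#' @param x An `ivd_result`.
#' @param ... Unused.
#' @return Tibble with `moment_nm`, `rom_deg`.
#' @export
tidy.ivd_result <- function(x, ...) x$rom_curve

#' One-row summary of a simulation result
#'
#' @param x An `ivd_result`.
#' @param ... Unused.
#' @return Tibble with load case, peak ROM, step count, time-step range,
#'   energy ledger closure and kinetic/internal ratio.
#' @export
glance.ivd_result <- function(x, ...) {
  tibble::tibble(
    load = x$load$name, moment_nm = x$load$moment,
    peak_rom_deg = x$peak_rom_deg, n_steps = x$n_steps,
    dt_min_s = x$dt_range[1], dt_max_s = x$dt_range[2],
    e_int = x$energy$E_int, w_ext = x$energy$W_ext,
    ke_ratio = x$energy$E_kin / max(x$energy$E_int, 1e-300),
    ledger_closure = x$energy$closure, status = x$status)
}

#' Tidy a wave-speed audit
#'
#' @param x An `ivd_wave_audit`.
#' @param ... Unused.
#' @return The per-element audit tibble.
#' @export
tidy.ivd_wave_audit <- function(x, ...) x$table

#' One-row wave-speed audit summary
#'
#' @param x An `ivd_wave_audit`.
#' @param ... Unused.
#' @return Tibble with mean/SD of the speed ratio and angular separation.
#' @export
glance.ivd_wave_audit <- function(x, ...) {
  tibble::tibble(load = x$load, n = x$n,
                 ratio_mean = x$ratio_mean, ratio_sd = x$ratio_sd,
                 angle_mean_deg = x$angle_mean, angle_sd_deg = x$angle_sd)
}

#' Tidy a calibration result
#'
#' @param x An `ivd_calibration`.
#' @param ... Unused.
#' @return Tibble with one row per free parameter: initial, estimated and
#'   (when known) true values.
#' @export
tidy.ivd_calibration <- function(x, ...) x$parameters

#' One-row calibration summary
#'
#' @param x An `ivd_calibration`.
#' @param ... Unused.
#' @return Tibble with objective values, evaluation count and convergence
#'   status.
#' @export
glance.ivd_calibration <- function(x, ...) {
  tibble::tibble(objective = x$objective, objective_initial = x$objective_initial,
                 n_evaluations = x$n_evaluations, convergence = x$convergence)
}

#' Plot a moment-rotation curve
#'
#' @param object An `ivd_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ivd_result <- function(object, ...) {
  ggplot2::ggplot(object$rom_curve,
                  ggplot2::aes(x = .data$moment_nm, y = .data$rom_deg)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Moment (N m)", y = "Rotation (deg)",
                  title = sprintf("%s, %g N m", object$load$name,
                                  object$load$moment)) +
    ggplot2::theme_minimal()
}

#' Plot a field summary (normalized histogram and ECDF)
#'
#' @param object An `ivd_field_summary`.
#' @param ... Unused.
#' @return A ggplot of the normalized histogram with the ECDF overlaid on a
#'   secondary axis.
#' @export
autoplot.ivd_field_summary <- function(object, ...) {
  h <- object$histogram
  xs <- sort(object$samples)
  ec <- tibble::tibble(x = xs, F = object$ecdf(xs))
  sc <- max(h$prob)
  ggplot2::ggplot() +
    ggplot2::geom_col(data = h, ggplot2::aes(x = .data$mid, y = .data$prob),
                      fill = "grey70", width = diff(object$breaks)[1]) +
    ggplot2::geom_step(data = ec,
                       ggplot2::aes(x = .data$x, y = .data$F * sc),
                       color = "firebrick") +
    ggplot2::scale_y_continuous(
      name = "Probability",
      sec.axis = ggplot2::sec_axis(~ . / sc, name = "ECDF")) +
    ggplot2::labs(x = object$variable) +
    ggplot2::theme_minimal()
}

#' Plot a wave-speed audit
#'
#' @param object An `ivd_wave_audit`.
#' @param ... Unused.
#' @return A two-panel ggplot: densities of the speed ratio and of the
#'   angular separation.
#' @export
autoplot.ivd_wave_audit <- function(object, ...) {
  tab <- object$table
  long <- rbind(
    tibble::tibble(metric = "speed ratio", value = tab$ratio),
    tibble::tibble(metric = "angular separation (deg)", value = tab$angle_deg))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "Density") +
    ggplot2::theme_minimal()
}

#' Plot ROM curves of a report
#'
#' @param object An `ivd_rom_report`.
#' @param ... Unused.
#' @return A ggplot of simulated (and reference) curves per load case.
#' @export
autoplot.ivd_rom_report <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$moment_nm, y = .data$rom_deg,
                               linetype = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~case, scales = "free_y") +
    ggplot2::labs(x = "Moment (N m)", y = "Rotation (deg)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
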