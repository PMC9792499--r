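# Field statistics and the wave-speed audit: per-element distributions of
# pressure and energy densities, ECDF comparisons between runs, and the
# elementwise comparison of the theoretically maximized wave speed against
# the five-direction approximation.

#' Summarize a per-element field
#'
#' Normalized histogram (probabilities summing to 1) and exact ECDF of a
#' peak-load element field of a simulation result.
#'
#' @param result An `ivd_result`, or a numeric vector of samples.
#' @param variable One of `"pressure"`, `"psi_iso"`, `"psi_aniso"` (ignored
#'   when `result` is already a vector).
#' @param region Optional region filter (`"AF"`, `"NP"`).
#' @param bins `"fd"` (Freedman-Diaconis) or an explicit vector of breaks
#'   (use shared breaks when comparing two runs).
#' @return Object of class `ivd_field_summary`: samples, histogram tibble
#'   (`mid`, `prob`), the ECDF function, and metadata.
#' @export
summarize_field <- function(result, variable = c("pressure", "psi_iso",
                                                 "psi_aniso"),
                            region = NULL, bins = "fd") {
  variable <- match.arg(variable)
  if (inherits(result, "ivd_result")) {
    el <- result$elements
    if (!is.null(region)) el <- el[el$region %in% region, ]
    if (nrow(el) == 0) stop("empty element selection")
    x <- switch(variable, pressure = el$pressure_pa,
                psi_iso = el$psi_iso, psi_aniso = el$psi_aniso)
  } else {
    x <- as.numeric(result)
    if (!length(x)) stop("empty element selection")
  }
  if (identical(bins, "fd")) {
    if (diff(range(x)) < .Machine$double.eps^0.5) {
      breaks <- c(x[1] - 0.5, x[1] + 0.5)
    } else {
      nb <- max(1L, grDevices::nclass.FD(x))
      breaks <- seq(min(x), max(x), length.out = nb + 1L)
    }
  } else breaks <- bins
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  structure(
    list(samples = x, variable = variable,
         histogram = tibble::tibble(mid = h$mids,
                                    prob = h$counts / length(x)),
         breaks = h$breaks,
         ecdf = stats::ecdf(x)),
    class = "ivd_field_summary")
}

#' @export
print.ivd_field_summary <- function(x, ...) {
  cat(sprintf("<ivd_field_summary> %s: n = %d, mean %.4g, sd %.4g\n",
              x$variable, length(x$samples), mean(x$samples),
              stats::sd(x$samples)))
  invisible(x)
}

#' Maximum ECDF difference between two field summaries
#'
#' The Kolmogorov-Smirnov-style maximum vertical distance between the two
#' empirical cumulative distribution functions, as a percentage.
#'
#' @param a,b [summarize_field()] results for the same variable.
#' @return Percentage in `[0, 100]`.
#' @examples
#' a <- summarize_field(c(1, 2))
#' b <- summarize_field(c(1, 3))
#' ecdf_max_difference(a, b)  # 50
#' @export
ecdf_max_difference <- function(a, b) {
  if (!identical(a$variable, b$variable))
    stop("summaries describe different variables")
  g <- sort(unique(c(a$samples, b$samples)))
  100 * max(abs(a$ecdf(g) - b$ecdf(g)))
}

#' Wave-speed audit of a simulation
#'
#' For every annulus element at peak load, computes the longitudinal wave
#' speed by dense direction maximization and by the five-fiber-direction
#' approximation, the elementwise speed ratio (theoretical/approximated, at
#' least 1 by construction), and the angular separation between the two
#' propagation directions (arccos of the absolute dot product: directions are
#' axes, so antipodes are identified).
#'
#' @param result An `ivd_result` with per-element peak fields.
#' @param rho0 Reference density used in the speed formula (cancels in the
#'   ratio), kg/m^3.
#' @param n_grid Angular grid resolution of the dense maximization.
#' @param elements Optional subset of element indices to audit.
#' @return Object of class `ivd_wave_audit`: a tibble (`element`, `v_theo`,
#'   `v_approx`, `ratio`, `angle_deg`) plus mean/SD summaries.
#' @export
wavespeed_audit <- function(result, rho0 = 1000, n_grid = 181L,
                            elements = NULL) {
  stopifnot(inherits(result, "ivd_result"))
  mesh <- result$mesh
  af <- which(mesh$region == "AF")
  if (!is.null(elements)) af <- intersect(af, elements)
  if (!length(af)) stop("no AF elements to audit")
  afmat <- result$materials$af
  n <- length(af)
  v_t <- v_a <- ang <- rep(NA_real_, n)
  failed <- 0L
  for (i in seq_len(n)) {
    e <- af[i]
    Fm <- matrix(result$F_peak[e, ], 3, 3)
    fb <- fiber_pair(mesh$M1[e, ], mesh$M2[e, ])
    ok <- tryCatch({
      st <- decompose_kinematics(Fm)
      bu <- elasticity_tensors(st, afmat, fb)
      th <- max_wave_speed_theoretical(st, bu, rho0, n_grid = n_grid)
      ap <- max_wave_speed_approx(st, bu, fb, rho0)
      v_t[i] <- th$v_max; v_a[i] <- ap$v_max
      d <- abs(sum(th$n_star * ap$n_star))
      ang[i] <- acos(min(max(d, -1), 1)) * 180 / pi
      TRUE
    }, error = function(err) FALSE)
    if (!ok) failed <- failed + 1L
  }
  keep <- !is.na(v_t)
  tab <- tibble::tibble(element = af[keep], v_theo = v_t[keep],
                        v_approx = v_a[keep],
                        ratio = v_t[keep] / v_a[keep],
                        angle_deg = ang[keep])
  structure(
    list(table = tab,
         ratio_mean = mean(tab$ratio), ratio_sd = stats::sd(tab$ratio),
         angle_mean = mean(tab$angle_deg), angle_sd = stats::sd(tab$angle_deg),
         n = nrow(tab), n_failed = failed,
         load = result$load$name),
    class = "ivd_wave_audit")
}

#' @export
print.ivd_wave_audit <- function(x, ...) {
  cat(sprintf(
    "<ivd_wave_audit> %s, n = %d AF elements%s\n  speed ratio (mean, SD): (%.4f, %.4f)\n  angular separation (mean, SD): (%.2f, %.2f) deg\n",
    x$load, x$n,
    if (x$n_failed) sprintf(" (%d failed, skipped)", x$n_failed) else "",
    x$ratio_mean, x$ratio_sd, x$angle_mean, x$angle_sd))
  invisible(x)
}

#' Range-of-motion comparison report
#'
#' Interpolates simulated moment-rotation curves onto a shared moment grid
#' and tabulates them against reference curves (for example experimental
#' means), with peak-ROM relative differences.
#'
#' @param results Named list of `ivd_result` objects (names are load cases),
#'   or a single result.
#' @param reference Optional reference tibble with columns `case`,
#'   `moment_nm`, `rom_deg`.
#' @return Object of class `ivd_rom_report` containing the long-format curve
#'   tibble and a per-case summary.
#' @export
rom_report <- function(results, reference = NULL) {
  if (inherits(results, "ivd_result")) {
    results <- stats::setNames(list(results), results$load$name)
  }
  curves <- do.call(rbind, lapply(names(results), function(nm) {
    rc <- results[[nm]]$rom_curve
    tibble::tibble(case = nm, moment_nm = rc$moment_nm, rom_deg = rc$rom_deg,
                   source = "simulated")
  }))
  summary <- tibble::tibble(
    case = names(results),
    peak_moment_nm = unname(vapply(results, function(r) r$load$moment, 0)),
    peak_rom_deg = unname(vapply(results, function(r) r$peak_rom_deg, 0)))
  if (!is.null(reference)) {
    if (!all(c("case", "moment_nm", "rom_deg") %in% names(reference)))
      stop("reference needs columns case, moment_nm, rom_deg")
    extra <- setdiff(unique(reference$case), names(results))
    if (length(extra))
      stop("reference contains load cases without simulations: ",
           paste(extra, collapse = ", "))
    refpk <- vapply(names(results), function(nm) {
      rr <- reference[reference$case == nm, ]
      if (!nrow(rr)) return(NA_real_)
      # linear interpolation preserves endpoints exactly
      stats::approx(rr$moment_nm, rr$rom_deg,
                    xout = summary$peak_moment_nm[summary$case == nm],
                    rule = 2)$y
    }, 0)
    refpk <- unname(refpk)
    summary$ref_peak_rom_deg <- refpk
    summary$rel_diff_pct <- 100 * abs(summary$peak_rom_deg - refpk) /
      pmax(abs(refpk), 1e-12)
    curves <- rbind(curves,
                    tibble::tibble(case = reference$case,
                                   moment_nm = reference$moment_nm,
                                   rom_deg = reference$rom_deg,
                                   source = "reference"))
  }
  structure(list(curves = curves, summary = summary),
            class = "ivd_rom_report")
}

#' @export
print.ivd_rom_report <- function(x, ...) {
  cat("<ivd_rom_report>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}
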