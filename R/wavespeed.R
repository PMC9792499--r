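# Acoustic-tensor longitudinal wave speeds and the explicit critical time
# step. Longitudinal (P-) waves take polarization parallel to propagation
# (m = n), so the squared speed along a unit direction n is
#   rho0 v^2 = J (c_ijkl + sigma_ik delta_jl) n_i n_j n_k n_l .

# spherical parametrization n(phi, theta), both angles in [0, pi)
.n_from_angles <- function(phi, theta) {
  cbind(cos(phi) * sin(theta), sin(phi) * sin(theta), cos(theta))
}

# squared speeds for many unit directions N (G x 3) at one state
.v2_grid <- function(bundle, N, rho0) {
  cm <- matrix(bundle$c_spat, 9, 9)
  NN <- N[, rep(1:3, each = 3), drop = FALSE] * N[, rep(1:3, times = 3), drop = FALSE]
  # NN columns follow flattened (p,q) = (q-1)*3+p with p fastest
  v2c <- rowSums((NN %*% t(cm)) * NN)
  nsn <- rowSums((N %*% bundle$sigma) * N)
  (bundle$J / rho0) * (v2c + nsn)
}

new_wave_result <- function(v_max, n_star, method, phi = NA_real_, theta = NA_real_) {
  structure(list(v_max = v_max, n_star = n_star, method = method,
                 phi_star = phi, theta_star = theta),
            class = "ivd_wave_result")
}

#' @export
print.ivd_wave_result <- function(x, ...) {
  cat(sprintf("<ivd_wave_result> v_max = %.6g m/s (%s), n* = (%.4f, %.4f, %.4f)\n",
              x$v_max, x$method, x$n_star[1], x$n_star[2], x$n_star[3]))
  invisible(x)
}

#' Longitudinal plane-wave speed along a direction
#'
#' Evaluates the P-wave speed
#' \eqn{v = \sqrt{(J/\rho_0)\,(c_{ijkl} + \sigma_{ik}\delta_{jl})\,
#' n_i n_j n_k n_l}} from a spatial elasticity bundle. A negative contraction
#' signals loss of rank-one convexity along `n` and raises an error.
#'
#' @param state An [decompose_kinematics()] result.
#' @param bundle An [elasticity_tensors()] result consistent with `state`.
#' @param n Unit propagation direction (spatial).
#' @param rho0 Reference density, kg/m^3.
#' @return Wave speed in m/s (moduli in Pa).
#' @examples
#' np <- material_preset("np_table1")
#' st <- decompose_kinematics(diag(3))
#' pwave_speed(st, elasticity_tensors(st, np), c(1, 0, 0), 1000)
#' @export
pwave_speed <- function(state, bundle, n, rho0) {
  n <- as.numeric(n)
  if (abs(sum(n^2) - 1) > 1e-8) stop("n must be a unit vector")
  v2 <- .v2_grid(bundle, matrix(n, 1, 3), rho0)
  if (v2 < 0)
    stop(sprintf(
      "material instability: loss of rank-one convexity along n = (%.4f, %.4f, %.4f)",
      n[1], n[2], n[3]))
  sqrt(v2)
}

#' Direction-maximized longitudinal wave speed (dense search)
#'
#' Maximizes the P-wave speed over the half-sphere parametrized by spherical
#' angles \eqn{\phi, \theta \in [0, \pi)}: a uniform angular grid (default
#' 181 x 181) followed by a derivative-free local polish from the best grid
#' point. This is the theoretical reference against which the cheap
#' five-direction approximation is audited.
#'
#' @inheritParams pwave_speed
#' @param n_grid Grid resolution per angle.
#' @param polish Run a Nelder-Mead refinement from the best grid point.
#' @return An `ivd_wave_result` with `method = "theoretical"` and the
#'   maximizing angles.
#' @export
max_wave_speed_theoretical <- function(state, bundle, rho0,
                                       n_grid = 181L, polish = TRUE) {
  ang <- seq(0, pi, length.out = n_grid + 1L)[seq_len(n_grid)]
  G <- expand.grid(phi = ang, theta = ang)
  N <- .n_from_angles(G$phi, G$theta)
  v2 <- .v2_grid(bundle, N, rho0)
  ib <- which.max(v2)
  best <- c(G$phi[ib], G$theta[ib])
  if (polish) {
    obj <- function(a) -.v2_grid(bundle, .n_from_angles(a[1], a[2]), rho0)
    op <- stats::optim(best, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-12, maxit = 400))
    if (-op$value > v2[ib]) {
      best <- op$par
      v2[ib] <- -op$value
    }
  }
  if (v2[ib] < 0) stop("material instability: all probed directions unstable")
  best <- best %% pi
  nst <- as.numeric(.n_from_angles(best[1], best[2]))
  new_wave_result(sqrt(v2[ib]), nst, "theoretical", best[1], best[2])
}

#' Five-direction set for the wave-speed approximation
#'
#' The candidate propagation directions built from the fiber pair:
#' \eqn{\{M_1, M_2, M_1 + M_2, M_1 - M_2, M_1 \times M_2\}}, each normalized
#' to unit length. Degenerate members (parallel fiber families make
#' \eqn{M_1 - M_2} and \eqn{M_1 \times M_2} vanish) are dropped.
#'
#' @param fibers A [fiber_pair()].
#' @return Matrix with one unit direction per row.
#' @export
direction_set <- function(fibers) {
  M1 <- fibers$M1; M2 <- fibers$M2
  cr <- c(M1[2] * M2[3] - M1[3] * M2[2],
          M1[3] * M2[1] - M1[1] * M2[3],
          M1[1] * M2[2] - M1[2] * M2[1])
  cand <- rbind(M1, M2, M1 + M2, M1 - M2, cr)
  nrm <- sqrt(rowSums(cand^2))
  keep <- nrm > 1e-10
  if (!any(keep)) stop("degenerate fiber pair: empty direction set")
  cand <- cand[keep, , drop = FALSE] / nrm[keep]
  rownames(cand) <- c("M1", "M2", "M1+M2", "M1-M2", "M1xM2")[keep]
  cand
}

#' Approximated maximum wave speed over the five fiber directions
#'
#' The computationally cheap surrogate for the dense direction search: the
#' maximum P-wave speed over the [direction_set()] candidates convected to
#' the current configuration (each reference direction `d` is evaluated along
#' the spatial direction `F d / |F d|`, so the candidate set tracks the
#' rotated and stretched fiber axes). By construction the result bounds the
#' theoretical maximum from below.
#'
#' @inheritParams pwave_speed
#' @param fibers A [fiber_pair()] (annulus elements).
#' @return An `ivd_wave_result` with `method = "approx"`.
#' @export
max_wave_speed_approx <- function(state, bundle, fibers, rho0) {
  N <- direction_set(fibers) %*% t(state$F)
  N <- N / sqrt(rowSums(N^2))
  v2 <- .v2_grid(bundle, N, rho0)
  ib <- which.max(v2)
  if (v2[ib] < 0) stop("material instability along all candidate directions")
  new_wave_result(sqrt(v2[ib]), as.numeric(N[ib, ]), "approx")
}

#' Maximum wave speed for isotropic elements
#'
#' Nucleus elements carry no fiber direction set; for an isotropic material
#' the extremal longitudinal speeds occur along the (spatial) principal
#' stretch directions, so the maximum over the three principal directions of
#' `C` (pushed forward by `F`) is taken.
#'
#' @inheritParams pwave_speed
#' @return An `ivd_wave_result` with `method = "approx"`.
#' @export
wave_speed_isotropic_max <- function(state, bundle, rho0) {
  ee <- eigen(state$C, symmetric = TRUE)
  N <- state$F %*% ee$vectors
  N <- t(N) / sqrt(colSums(N^2))
  v2 <- .v2_grid(bundle, N, rho0)
  ib <- which.max(v2)
  if (v2[ib] < 0) stop("material instability along principal directions")
  new_wave_result(sqrt(v2[ib]), as.numeric(N[ib, ]), "approx")
}

#' Critical time step of explicit integration
#'
#' \eqn{\Delta t_{crit} = F\, l_c / v_{max}} with a multiplicative safety
#' factor (default 0.9): the transit time of the fastest longitudinal wave
#' across the characteristic element length, slightly reduced to buffer the
#' estimate.
#'
#' @param l_c Characteristic element length (m).
#' @param v_max Maximum wave speed (m/s).
#' @param factor Safety factor in (0, 1].
#' @return Object of class `ivd_timestep`: list with `dt_crit` (s), `l_c`,
#'   `factor`.
#' @examples
#' critical_timestep(1e-3, 5, 0.9)$dt_crit  # 1.8e-4 s
#' @export
critical_timestep <- function(l_c, v_max, factor = 0.9) {
  if (any(l_c <= 0)) stop("l_c must be positive")
  if (any(v_max <= 0)) stop("v_max must be positive")
  if (factor <= 0 || factor > 1) stop("factor must be in (0, 1]")
  structure(list(dt_crit = factor * l_c / v_max, l_c = l_c, factor = factor),
            class = "ivd_timestep")
}
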