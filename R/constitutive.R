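# helpers shared by the pointwise constitutive API

.state_check <- function(state) {
  if (!inherits(state, "ivd_deformation"))
    stop("state must come from decompose_kinematics()")
}

.fibers_rows <- function(fibers) {
  list(M1 = matrix(fibers$M1, 1, 3), M2 = matrix(fibers$M2, 1, 3))
}

.point_eval <- function(state, mat, fibers = NULL) {
  pars <- mat_pars(mat)
  kin <- batch_kin(matrix(as.numeric(state$F), 1, 9))
  if (inherits(mat, "ivd_af_material")) {
    if (is.null(fibers)) stop("annulus material requires a fiber_pair")
    fr <- .fibers_rows(fibers)
    st <- batch_stress(kin, pars, fr$M1, fr$M2)
  } else {
    st <- batch_stress(kin, pars)
  }
  list(kin = kin, st = st, pars = pars)
}

new_energy_breakdown <- function(psi_iso, psi_vol, psi_aniso, IM1, IM2) {
  structure(list(psi_iso = psi_iso, psi_vol = psi_vol, psi_aniso = psi_aniso,
                 IM1_bar = IM1, IM2_bar = IM2),
            class = "ivd_energy")
}

#' @export
print.ivd_energy <- function(x, ...) {
  cat(sprintf(
    "<ivd_energy> iso %.6g  vol %.6g  aniso %.6g Pa\n",
    x$psi_iso, x$psi_vol, x$psi_aniso))
  if (!is.na(x$IM1_bar))
    cat(sprintf("  fiber invariants: %.6g, %.6g\n", x$IM1_bar, x$IM2_bar))
  invisible(x)
}

#' Strain energy density of the nucleus pulposus
#'
#' Evaluates the compressible Mooney-Rivlin energy split
#' \eqn{\psi_{iso} = b_{10}(\bar I_1 - 3) + b_{01}(\bar I_2 - 3)} and
#' \eqn{\psi_{vol} = \tfrac{k}{2}(J-1)^2}. The anisotropic term is zero for
#' this isotropic tissue.
#'
#' @param state An [decompose_kinematics()] result.
#' @param mat An [np_material()].
#' @return An `ivd_energy` breakdown (Pa).
#' @examples
#' np <- material_preset("np_table1")
#' energy_np(decompose_kinematics(diag(c(2, 1, 1))), np)
#' @export
energy_np <- function(state, mat) {
  .state_check(state)
  if (!inherits(mat, "ivd_np_material")) stop("mat must be an np_material")
  ev <- .point_eval(state, mat)
  new_energy_breakdown(ev$st$psi_iso[1], ev$st$psi_vol[1], 0, NA_real_, NA_real_)
}

#' Strain energy density of the annulus fibrosus
#'
#' Adds to the Mooney-Rivlin matrix terms the tension-only exponential fiber
#' energy \eqn{\sum_i \frac{a_1}{a_2}[\exp(a_2\langle \bar I_{M_i} -
#' 1\rangle^2) - 1]} for the two collagen families.
#'
#' @param state An [decompose_kinematics()] result.
#' @param mat An [af_material()].
#' @param fibers A [fiber_pair()].
#' @return An `ivd_energy` breakdown (Pa) including the fiber invariants
#'   \eqn{\bar I_{M_1}, \bar I_{M_2}}.
#' @export
energy_af <- function(state, mat, fibers) {
  .state_check(state)
  if (!inherits(mat, "ivd_af_material")) stop("mat must be an af_material")
  ev <- .point_eval(state, mat, fibers)
  new_energy_breakdown(ev$st$psi_iso[1], ev$st$psi_vol[1], ev$st$psi_aniso[1],
                       ev$st$IM1[1], ev$st$IM2[1])
}

#' Second Piola-Kirchhoff stress
#'
#' Analytic stress \eqn{S = 2\,\partial\Psi/\partial C} for either disc
#' tissue, using the decoupled volumetric/distortional split with the
#' deviatoric projector (no numerical differentiation).
#'
#' @param state An [decompose_kinematics()] result.
#' @param mat An `ivd_material`.
#' @param fibers A [fiber_pair()]; required iff `mat` is an annulus material.
#' @return Symmetric 3x3 matrix (Pa).
#' @examples
#' np <- material_preset("np_table1")
#' pk2_stress(decompose_kinematics(1.1 * diag(3)), np)
#' @export
pk2_stress <- function(state, mat, fibers = NULL) {
  .state_check(state)
  ev <- .point_eval(state, mat, fibers)
  mat3_from_sym6(ev$st$S[1, ])
}

#' Cauchy stress push-forward
#'
#' \eqn{\sigma = J^{-1} F S F^T}.
#'
#' @param S Symmetric 3x3 second Piola-Kirchhoff stress.
#' @param F 3x3 deformation gradient with positive determinant.
#' @return Symmetric 3x3 Cauchy stress (same units as `S`).
#' @export
cauchy_stress <- function(S, F) {
  J <- det(F)
  if (J <= 0) stop(sprintf("invalid deformation: det(F) = %g", J))
  (F %*% S %*% t(F)) / J
}

#' Mechanical pressure
#'
#' \eqn{p = -\mathrm{tr}\,\sigma / 3}; positive in compression.
#'
#' @param sigma Symmetric 3x3 Cauchy stress.
#' @return Scalar pressure (same units as `sigma`).
#' @export
pressure <- function(sigma) -sum(diag(sigma)) / 3

# 9x9 flattened-tensor building blocks for the analytic elasticity tensor.
# Flattening: row index (q-1)*3+p represents component (p,q).
.tensor_outer <- function(A, B) as.numeric(A) %o% as.numeric(B) # A x B

.tensor_sym_open <- function(A, B) {
  # (A (x) B)_sym,pqrs = 1/2 (A_pr B_qs + A_ps B_qr), flattened to 9x9
  M <- matrix(0, 9, 9)
  for (q in 1:3) for (p in 1:3) for (s in 1:3) for (r in 1:3) {
    M[(q - 1) * 3 + p, (s - 1) * 3 + r] <-
      0.5 * (A[p, r] * B[q, s] + A[p, s] * B[q, r])
  }
  M
}

#' Material and spatial elasticity tensors
#'
#' Returns the analytic stress and tangent package at a deformation state:
#' second Piola-Kirchhoff stress `S`, Cauchy stress `sigma`, the material
#' elasticity tensor \eqn{\mathbb{C} = 2\,\partial S/\partial C} and its
#' spatial push-forward
#' \eqn{c_{ijkl} = J^{-1} F_{iP} F_{jQ} F_{kR} F_{lS} \mathbb{C}_{PQRS}}.
#' The material tensor is assembled from the closed-form decoupled
#' expressions (volumetric Cinv x Cinv terms, deviatoric projector applied to
#' the fictitious distortional tangent, and rank-four fiber terms); both
#' tensors carry minor and major symmetries.
#'
#' @inheritParams pk2_stress
#' @return Object of class `ivd_elasticity`: list with `S`, `sigma` (3x3, Pa),
#'   `C_mat`, `c_spat` (3x3x3x3 arrays, Pa) and `J`.
#' @export
elasticity_tensors <- function(state, mat, fibers = NULL) {
  .state_check(state)
  ev <- .point_eval(state, mat, fibers)
  pars <- ev$pars
  J <- state$J
  C <- state$C
  Ci <- mat3_from_sym6(ev$kin$Cinv[1, ])
  Jm23 <- J^(-2 / 3)
  I3 <- diag(3)

  # distortional fictitious stress Sbar (function of Cbar)
  g1 <- 2 * (pars$p10 + ev$kin$I1b[1] * pars$p01)
  g2 <- -2 * pars$p01
  Sb <- g1 * I3 + g2 * Jm23 * C
  # fictitious tangent 2 dSbar/dCbar, flattened
  Cf <- 4 * pars$p01 * (.tensor_outer(I3, I3) - .tensor_sym_open(I3, I3))
  if (inherits(mat, "ivd_af_material")) {
    for (fam in 1:2) {
      M <- if (fam == 1) fibers$M1 else fibers$M2
      IM <- if (fam == 1) ev$st$IM1[1] else ev$st$IM2[1]
      fp <- if (fam == 1) ev$st$fp1[1] else ev$st$fp2[1]
      e <- max(IM - 1, 0)
      Sb <- Sb + 2 * fp * (M %o% M)
      if (IM >= 1) {
        fpp <- 2 * pars$a1 * exp(pars$a2 * e^2) * (1 + 2 * pars$a2 * e^2)
        MM <- M %o% M
        Cf <- Cf + 4 * fpp * .tensor_outer(MM, MM)
      }
    }
  }
  trSbC <- sum(Sb * C)
  S_dist <- Jm23 * (Sb - (trSbC / 3) * Ci)

  # deviatoric projector P = I_sym - 1/3 Cinv x C  (flattened)
  P <- .tensor_sym_open(I3, I3) - (1 / 3) * .tensor_outer(Ci, C)
  Ptil <- .tensor_sym_open(Ci, Ci) - (1 / 3) * .tensor_outer(Ci, Ci)

  C_iso <- P %*% (Jm23^2 * Cf) %*% t(P) +
    (2 / 3) * Jm23 * trSbC * Ptil -
    (2 / 3) * (.tensor_outer(Ci, S_dist) + .tensor_outer(S_dist, Ci))

  Up <- pars$k * (J - 1)
  Upp <- pars$k
  C_vol <- J * (Up + J * Upp) * .tensor_outer(Ci, Ci) -
    2 * J * Up * .tensor_sym_open(Ci, Ci)

  Cm9 <- C_iso + C_vol
  Fk <- kronecker(state$F, state$F) # vec(F X F') = (F (x) F) vec(X)
  cs9 <- (Fk %*% Cm9 %*% t(Fk)) / J

  S <- mat3_from_sym6(ev$st$S[1, ])
  structure(
    list(
      S = S,
      sigma = cauchy_stress(S, state$F),
      C_mat = array(Cm9, c(3, 3, 3, 3)),
      c_spat = array(cs9, c(3, 3, 3, 3)),
      J = J
    ),
    class = "ivd_elasticity"
  )
}

#' @export
print.ivd_elasticity <- function(x, ...) {
  cat("<ivd_elasticity> J =", format(x$J, digits = 6),
      " |S| =", format(norm(x$S, "F"), digits = 6), "Pa\n")
  invisible(x)
}
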