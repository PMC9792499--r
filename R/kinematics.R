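#' Macaulay bracket
#'
#' \eqn{\langle x \rangle = (|x| + x)/2 = \max(x, 0)}, used to switch off the
#' collagen fiber response in compression.
#'
#' @param x Numeric vector.
#' @return `pmax(x, 0)`.
#' @examples
#' macaulay(c(-1, 0, 2))
#' @export
macaulay <- function(x) (abs(x) + x) / 2

#' Decompose a deformation gradient
#'
#' Splits a deformation gradient `F` into its volumetric and distortional
#' parts: \eqn{J = \det F}, \eqn{C = F^T F},
#' \eqn{\bar F = J^{-1/3} F}, \eqn{\bar C = \bar F^T \bar F} (unimodular),
#' and the distortional invariants \eqn{\bar I_1 = \mathrm{tr}\,\bar C},
#' \eqn{\bar I_2 = \tfrac12[(\mathrm{tr}\,\bar C)^2 -
#' \mathrm{tr}\,\bar C^2]}.
#'
#' @param F A real 3x3 matrix with positive determinant.
#' @return An object of class `ivd_deformation`: list with `F`, `J`, `C`,
#'   `F_bar`, `C_bar`, `I1_bar`, `I2_bar`.
#' @examples
#' st <- decompose_kinematics(diag(c(2, 1, 1)))
#' st$J        # 2
#' st$I1_bar   # 6 * 2^(-2/3)
#' @export
decompose_kinematics <- function(F) {
  if (!is.matrix(F) || !identical(dim(F), c(3L, 3L)) || !all(is.finite(F)))
    stop("F must be a finite 3x3 matrix")
  J <- det(F)
  if (J <= 0)
    stop(sprintf("invalid deformation: det(F) = %g must be positive", J))
  kin <- batch_kin(matrix(as.numeric(F), 1, 9))
  structure(
    list(
      F = F,
      J = J,
      C = mat3_from_sym6(kin$C[1, ]),
      F_bar = J^(-1 / 3) * F,
      C_bar = kin$Jm23[1] * mat3_from_sym6(kin$C[1, ]),
      I1_bar = kin$I1b[1],
      I2_bar = kin$I2b[1]
    ),
    class = "ivd_deformation"
  )
}

#' @export
print.ivd_deformation <- function(x, ...) {
  cat("<ivd_deformation> J =", format(x$J, digits = 6),
      " I1_bar =", format(x$I1_bar, digits = 6),
      " I2_bar =", format(x$I2_bar, digits = 6), "\n")
  invisible(x)
}

#' Collagen fiber direction pair
#'
#' Bundles the two unit reference directions of the annulus collagen fiber
#' families. With a local orthonormal basis
#' \eqn{\{\hat e_1, \hat e_2, \hat e_3\}} (circumferential, axial, radial) and
#' fiber angle \eqn{\Phi} about the transverse plane, the families are
#' \eqn{M_1 = (\cos\Phi, \sin\Phi, 0)} and
#' \eqn{M_2 = (\cos\Phi, -\sin\Phi, 0)} in that basis.
#'
#' @param M1,M2 Unit 3-vectors (reference configuration).
#' @return Object of class `ivd_fiber_pair`.
#' @export
fiber_pair <- function(M1, M2) {
  M1 <- as.numeric(M1); M2 <- as.numeric(M2)
  if (length(M1) != 3 || length(M2) != 3) stop("fiber directions must be 3-vectors")
  n1 <- sqrt(sum(M1^2)); n2 <- sqrt(sum(M2^2))
  if (abs(n1 - 1) > 1e-8 || abs(n2 - 1) > 1e-8)
    stop("fiber directions must be unit length")
  degenerate <- min(sum((M1 - M2)^2), sum((M1 + M2)^2)) < 1e-16
  structure(list(M1 = M1, M2 = M2, degenerate = degenerate),
            class = "ivd_fiber_pair")
}

#' @describeIn fiber_pair Construct the pair from the fiber angle `phi`
#'   (degrees) and a local orthonormal basis (columns `e1`, `e2`, `e3`;
#'   default the global axes). A zero angle collapses both families onto
#'   `e1` and is flagged `degenerate`.
#' @param phi Fiber angle in degrees.
#' @param basis 3x3 matrix whose columns are the local orthonormal basis.
#' @export
fiber_pair_from_angle <- function(phi, basis = diag(3)) {
  cs <- cos(phi * pi / 180); sn <- sin(phi * pi / 180)
  M1 <- basis %*% c(cs, sn, 0)
  M2 <- basis %*% c(cs, -sn, 0)
  M1 <- M1 / sqrt(sum(M1^2)); M2 <- M2 / sqrt(sum(M2^2))
  p <- structure(list(M1 = as.numeric(M1), M2 = as.numeric(M2),
                      degenerate = FALSE), class = "ivd_fiber_pair")
  p$degenerate <- min(sum((p$M1 - p$M2)^2), sum((p$M1 + p$M2)^2)) < 1e-16
  p
}
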