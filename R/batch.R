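# Internal vectorized constitutive core.
#
# All per-element quantities are held as matrices with one row per element:
#   - full 3x3 tensors as E x 9 (column-major: 11,21,31,12,22,32,13,23,33)
#   - symmetric 3x3 tensors as E x 6 (order 11,22,33,12,13,23)
# The pointwise user-facing functions wrap this core with E = 1, so there is
# a single implementation of the material model.

.S9 <- c(1L, 4L, 5L, 4L, 2L, 6L, 5L, 6L, 3L) # sym6 -> full9 expansion

sym6_to9 <- function(S6) S6[, .S9, drop = FALSE]

mat3_from_row <- function(m9) matrix(m9, 3, 3)
row_from_mat3 <- function(M) as.numeric(M)
sym6_from_mat3 <- function(M) c(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])
mat3_from_sym6 <- function(s6) matrix(s6[.S9], 3, 3)

# C = A %*% B rowwise for E x 9 tensor stacks
mat3_mul_batch <- function(A, B) {
  E <- nrow(A)
  out <- matrix(0, E, 9)
  for (j in 1:3) for (i in 1:3) {
    cidx <- (j - 1L) * 3L + i
    out[, cidx] <- A[, i] * B[, cidx - i + 1L] +
      A[, i + 3L] * B[, cidx - i + 2L] +
      A[, i + 6L] * B[, cidx - i + 3L]
  }
  out
}

# quadratic form v' S v for sym6 stack and E x 3 vectors
sym6_quad <- function(S6, V) {
  S6[, 1] * V[, 1]^2 + S6[, 2] * V[, 2]^2 + S6[, 3] * V[, 3]^2 +
    2 * (S6[, 4] * V[, 1] * V[, 2] + S6[, 5] * V[, 1] * V[, 3] +
           S6[, 6] * V[, 2] * V[, 3])
}

# double contraction A : B of two sym6 stacks
sym6_ddot <- function(A, B) {
  A[, 1] * B[, 1] + A[, 2] * B[, 2] + A[, 3] * B[, 3] +
    2 * (A[, 4] * B[, 4] + A[, 5] * B[, 5] + A[, 6] * B[, 6])
}

batch_det9 <- function(F) {
  F[, 1] * (F[, 5] * F[, 9] - F[, 8] * F[, 6]) -
    F[, 4] * (F[, 2] * F[, 9] - F[, 8] * F[, 3]) +
    F[, 7] * (F[, 2] * F[, 6] - F[, 5] * F[, 3])
}

# kinematic scalars/tensors from an E x 9 deformation-gradient stack
batch_kin <- function(Fm) {
  J <- batch_det9(Fm)
  C11 <- Fm[, 1]^2 + Fm[, 2]^2 + Fm[, 3]^2
  C22 <- Fm[, 4]^2 + Fm[, 5]^2 + Fm[, 6]^2
  C33 <- Fm[, 7]^2 + Fm[, 8]^2 + Fm[, 9]^2
  C12 <- Fm[, 1] * Fm[, 4] + Fm[, 2] * Fm[, 5] + Fm[, 3] * Fm[, 6]
  C13 <- Fm[, 1] * Fm[, 7] + Fm[, 2] * Fm[, 8] + Fm[, 3] * Fm[, 9]
  C23 <- Fm[, 4] * Fm[, 7] + Fm[, 5] * Fm[, 8] + Fm[, 6] * Fm[, 9]
  C <- cbind(C11, C22, C33, C12, C13, C23, deparse.level = 0)
  detC <- J^2
  # adjugate of symmetric C
  Ci <- cbind(
    C22 * C33 - C23^2,
    C11 * C33 - C13^2,
    C11 * C22 - C12^2,
    C13 * C23 - C12 * C33,
    C12 * C23 - C13 * C22,
    C12 * C13 - C11 * C23
  ) / detC
  I1 <- C11 + C22 + C33
  trC2 <- C11^2 + C22^2 + C33^2 + 2 * (C12^2 + C13^2 + C23^2)
  I2 <- 0.5 * (I1^2 - trC2)
  Jm23 <- J^(-2 / 3)
  list(F = Fm, J = J, C = C, Cinv = Ci, I1 = I1, I2 = I2, trC2 = trC2,
       Jm23 = Jm23, I1b = Jm23 * I1, I2b = Jm23^2 * I2)
}

# stress + energy densities; M1/M2 are E x 3 unit reference fiber directions
# (NULL for the isotropic NP). pars from mat_pars().
batch_stress <- function(kin, pars, M1 = NULL, M2 = NULL) {
  E <- length(kin$J)
  p10 <- pars$p10; p01 <- pars$p01; k <- pars$k
  g1 <- 2 * (p10 + kin$I1b * p01)
  g2 <- -2 * p01
  # fictitious distortional stress Sbar = g1 I + g2 Cbar + 2 sum f' Mi x Mi
  Sb <- kin$Jm23 * g2 * kin$C
  Sb[, 1:3] <- Sb[, 1:3] + g1
  psi_aniso <- numeric(E)
  IM1 <- IM2 <- fp1 <- fp2 <- e1 <- e2 <- x1 <- x2 <- NULL
  if (!is.null(M1)) {
    IM1 <- kin$Jm23 * sym6_quad(kin$C, M1)
    IM2 <- kin$Jm23 * sym6_quad(kin$C, M2)
    e1 <- (abs(IM1 - 1) + IM1 - 1) / 2
    e2 <- (abs(IM2 - 1) + IM2 - 1) / 2
    x1 <- exp(pars$a2 * e1^2); x2 <- exp(pars$a2 * e2^2)
    fp1 <- 2 * pars$a1 * e1 * x1
    fp2 <- 2 * pars$a1 * e2 * x2
    psi_aniso <- (pars$a1 / pars$a2) * (x1 - 1 + x2 - 1)
    Sb <- Sb + 2 * fp1 * cbind(M1[, 1]^2, M1[, 2]^2, M1[, 3]^2,
                               M1[, 1] * M1[, 2], M1[, 1] * M1[, 3],
                               M1[, 2] * M1[, 3]) +
      2 * fp2 * cbind(M2[, 1]^2, M2[, 2]^2, M2[, 3]^2,
                      M2[, 1] * M2[, 2], M2[, 1] * M2[, 3],
                      M2[, 2] * M2[, 3])
  }
  trSbC <- sym6_ddot(Sb, kin$C)
  S <- k * (kin$J - 1) * kin$J * kin$Cinv +
    kin$Jm23 * (Sb - (trSbC / 3) * kin$Cinv)
  list(
    S = S,
    psi_iso = p10 * (kin$I1b - 3) + p01 * (kin$I2b - 3),
    psi_vol = 0.5 * k * (kin$J - 1)^2,
    psi_aniso = psi_aniso,
    IM1 = IM1, IM2 = IM2, fp1 = fp1, fp2 = fp2,
    e1 = e1, e2 = e2, x1 = x1, x2 = x2, trSbC = trSbC
  )
}

# Cauchy stress stack from PK2 stack
batch_cauchy <- function(Fm, S6, J) {
  P <- mat3_mul_batch(Fm, sym6_to9(S6)) # F S
  Ft <- Fm[, c(1L, 4L, 7L, 2L, 5L, 8L, 3L, 6L, 9L), drop = FALSE]
  sig9 <- mat3_mul_batch(P, Ft) / J
  cbind(sig9[, 1], sig9[, 5], sig9[, 9], sig9[, 4], sig9[, 7], sig9[, 8])
}

# Longitudinal (P-) wave squared speed along per-element spatial directions n
# (E x 3, unit length), using the analytic rank-one directional second
# derivative of the strain energy: C : (w x w) : (w x w) = 4 d^2/dt^2
# Psi(C + t w x w) with w = F' n, which avoids forming the full elasticity
# tensor in the per-step solver path.
#   v^2 = (4 g'' + J n.sigma.n) / rho0
batch_v2_dir <- function(kin, st, pars, sigma6, N, M1 = NULL, M2 = NULL) {
  Fm <- kin$F
  w1 <- Fm[, 1] * N[, 1] + Fm[, 2] * N[, 2] + Fm[, 3] * N[, 3]
  w2 <- Fm[, 4] * N[, 1] + Fm[, 5] * N[, 2] + Fm[, 6] * N[, 3]
  w3 <- Fm[, 7] * N[, 1] + Fm[, 8] * N[, 2] + Fm[, 9] * N[, 3]
  W <- cbind(w1, w2, w3)
  al <- sym6_quad(kin$Cinv, W)
  be <- w1^2 + w2^2 + w3^2
  ga <- sym6_quad(kin$C, W)
  beb <- kin$Jm23 * be
  gab <- kin$Jm23^2 * ga
  gpp <- 0.25 * pars$k * kin$J * al^2 +
    pars$p10 * ((4 / 9) * kin$I1b * al^2 - (2 / 3) * al * beb) +
    pars$p01 * ((10 / 9) * kin$I2b * al^2 -
                  (4 / 3) * al * (kin$I1b * beb - gab))
  if (!is.null(M1)) {
    for (fam in 1:2) {
      M <- if (fam == 1) M1 else M2
      IM <- if (fam == 1) st$IM1 else st$IM2
      fp <- if (fam == 1) st$fp1 else st$fp2
      e <- if (fam == 1) st$e1 else st$e2
      xx <- if (fam == 1) st$x1 else st$x2
      # one-sided tension branch (stiffness 2*a1 at IM = 1)
      fpp <- (2 * pars$a1) * xx * (1 + 2 * pars$a2 * e^2) * (IM >= 1)
      s <- (W[, 1] * M[, 1] + W[, 2] * M[, 2] + W[, 3] * M[, 3])^2
      sb <- kin$Jm23 * s
      IMp <- sb - al * IM / 3
      IMpp <- (4 / 9) * IM * al^2 - (2 / 3) * al * sb
      gpp <- gpp + fpp * IMp^2 + fp * IMpp
    }
  }
  (4 * gpp + kin$J * sym6_quad(sigma6, N)) / pars$rho0
}

# closed-form eigenvalues of a symmetric 3x3 stack (ascending columns)
batch_sym_eigval <- function(S6) {
  q <- (S6[, 1] + S6[, 2] + S6[, 3]) / 3
  p2 <- (S6[, 1] - q)^2 + (S6[, 2] - q)^2 + (S6[, 3] - q)^2 +
    2 * (S6[, 4]^2 + S6[, 5]^2 + S6[, 6]^2)
  p <- sqrt(p2 / 6)
  e1 <- e2 <- e3 <- q
  nz <- p > 1e-300
  if (any(nz)) {
    B <- (S6[nz, , drop = FALSE] - cbind(q[nz], q[nz], q[nz], 0, 0, 0)) / p[nz]
    detB <- B[, 1] * (B[, 2] * B[, 3] - B[, 6]^2) -
      B[, 4] * (B[, 4] * B[, 3] - B[, 6] * B[, 5]) +
      B[, 5] * (B[, 4] * B[, 6] - B[, 2] * B[, 5])
    r <- pmin(pmax(detB / 2, -1), 1)
    ph <- acos(r) / 3
    big <- q[nz] + 2 * p[nz] * cos(ph)
    sml <- q[nz] + 2 * p[nz] * cos(ph + 2 * pi / 3)
    mid <- 3 * q[nz] - big - sml
    e1[nz] <- sml; e2[nz] <- mid; e3[nz] <- big
  }
  cbind(e1, e2, e3)
}

# Max principal-direction P-wave squared speed for isotropic elements,
# expressed through the eigenvalues of C only (no eigenvectors needed):
# along the spatial principal direction with squared stretch lam2,
#   w = F' n has  alpha = 1, beta = lam2, gamma = lam2^2,
#   n.sigma.n = principal Cauchy stress = lam2 * S_princ / J.
batch_v2_principal_max <- function(kin, st, pars) {
  lam2 <- batch_sym_eigval(kin$C)
  g1 <- 2 * (pars$p10 + kin$I1b * pars$p01)
  g2 <- -2 * pars$p01
  out <- matrix(0, length(kin$J), 3)
  for (i in 1:3) {
    l2 <- lam2[, i]
    al <- 1
    beb <- kin$Jm23 * l2
    gab <- kin$Jm23^2 * l2^2
    gpp <- 0.25 * pars$k * kin$J +
      pars$p10 * ((4 / 9) * kin$I1b - (2 / 3) * beb) +
      pars$p01 * ((10 / 9) * kin$I2b - (4 / 3) * (kin$I1b * beb - gab))
    Sp <- pars$k * (kin$J - 1) * kin$J / l2 +
      kin$Jm23 * (g1 + g2 * kin$Jm23 * l2 - st$trSbC / (3 * l2))
    sig_p <- l2 * Sp / kin$J
    out[, i] <- (4 * gpp + kin$J * sig_p) / pars$rho0
  }
  out[, 1] <- pmax(out[, 1], out[, 2], out[, 3])
  out[, 1, drop = TRUE]
}
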