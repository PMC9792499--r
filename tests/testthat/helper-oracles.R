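# Shared fixtures and independent finite-difference oracles.

table1_np <- function() material_preset("np_table1")
table1_af <- function() material_preset("af_table1")

# random admissible deformation gradient (moderate distortion, J > 0)
random_F <- function(sd = 0.15) {
  repeat {
    F <- diag(3) + matrix(stats::rnorm(9, sd = sd), 3, 3)
    if (det(F) > 0.35) return(F)
  }
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# total strain energy density as a function of C (via the symmetric square
# root), the basis of the finite-difference stress/elasticity oracles
psi_of_C <- function(C, mat, fibers = NULL) {
  ee <- eigen(C, symmetric = TRUE)
  F <- ee$vectors %*% diag(sqrt(ee$values)) %*% t(ee$vectors)
  st <- decompose_kinematics(F)
  en <- if (inherits(mat, "ivd_af_material")) energy_af(st, mat, fibers)
        else energy_np(st, mat)
  en$psi_iso + en$psi_vol + en$psi_aniso
}

# central finite-difference PK2 stress: S_ij = 2 dPsi/dC_ij (symmetric pair
# perturbation makes the central difference equal S directly)
fd_pk2 <- function(C, mat, fibers = NULL, h = 1e-6) {
  S <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3) {
    dC <- matrix(0, 3, 3)
    dC[i, j] <- dC[i, j] + h
    dC[j, i] <- dC[j, i] + h
    d <- (psi_of_C(C + dC, mat, fibers) - psi_of_C(C - dC, mat, fibers)) / (2 * h)
    S[i, j] <- S[j, i] <- d
  }
  S
}

pk2_of_C <- function(C, mat, fibers = NULL) {
  ee <- eigen(C, symmetric = TRUE)
  F <- ee$vectors %*% diag(sqrt(ee$values)) %*% t(ee$vectors)
  pk2_stress(decompose_kinematics(F), mat, fibers)
}

# central finite-difference material elasticity: C_ijkl = 2 dS_ij/dC_kl
fd_cmat <- function(C, mat, fibers = NULL, h = 1e-6) {
  A <- array(0, c(3, 3, 3, 3))
  for (k in 1:3) for (l in k:3) {
    dC <- matrix(0, 3, 3)
    dC[k, l] <- dC[k, l] + h
    dC[l, k] <- dC[l, k] + h
    dS <- (pk2_of_C(C + dC, mat, fibers) - pk2_of_C(C - dC, mat, fibers)) / (2 * h)
    A[, , k, l] <- dS
    A[, , l, k] <- dS
  }
  A
}

# small segments reused across solver tests (cached per session)
.test_cache <- new.env()

coarse_mesh <- function() {
  if (is.null(.test_cache$coarse))
    .test_cache$coarse <- generate_segment(segment_spec(element_size = 6))
  .test_cache$coarse
}

# desk-scale disc: moments on it are geometrically scaled (about 1 N*m plays
# the role of 5 N*m on the anatomical segment)
tiny_mesh <- function() {
  if (is.null(.test_cache$tiny))
    .test_cache$tiny <- generate_segment(
      segment_spec(r_lat = 12, r_ap = 9, h_ant = 6.5, h_post = 6,
                   element_size = 5))
  .test_cache$tiny
}

# one quasi-static flexion run on the desk-scale disc, shared across test files
flexion_tiny_result <- function() {
  if (is.null(.test_cache$flexion_tiny))
    .test_cache$flexion_tiny <- run_explicit(
      tiny_mesh(), table1_np(), table1_af(), load_case("flexion", 1),
      solver_controls(ramp_time = 0.015))
  .test_cache$flexion_tiny
}
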