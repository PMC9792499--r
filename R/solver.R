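# Total-Lagrangian explicit quasi-static solver on linear tetrahedra.
#
# Units: meshes are in mm and converted to SI (m, kg, s, Pa) on setup;
# moments in N*m. The cranial vertebra is a rigid 6-DOF body carrying the
# ramped moment; the caudal vertebra is rigid and may only translate in the
# moment plane (all rotations locked), mirroring cadaveric test fixtures.

#' Load case definition
#'
#' A pure moment of given magnitude about an axis through the disc centroid:
#' flexion/extension about the lateral axis e1 (normal to the sagittal
#' plane, opposite signs), lateral bending about the anterior-posterior axis
#' e2 (normal to the frontal plane), axial rotation about the cranial-caudal
#' axis e3 (normal to the transverse plane).
#'
#' @param name Load case name.
#' @param moment Moment magnitude in N*m (default 5).
#' @param axis Optional unit axis override.
#' @return Object of class `ivd_load_case`.
#' @examples
#' load_case("flexion")
#' @export
load_case <- function(name = c("flexion", "extension", "lateral_bending",
                               "axial_rotation"),
                      moment = 5, axis = NULL) {
  name <- match.arg(name)
  if (moment <= 0) stop("moment must be positive")
  if (is.null(axis)) {
    axis <- switch(name,
                   flexion = c(1, 0, 0),
                   extension = c(-1, 0, 0),
                   lateral_bending = c(0, 1, 0),
                   axial_rotation = c(0, 0, 1))
  }
  axis <- axis / sqrt(sum(axis^2))
  structure(list(name = name, moment = moment, axis = axis),
            class = "ivd_load_case")
}

#' Explicit solver controls
#'
#' Numerical controls of [run_explicit()]. The moment is ramped with a C2
#' quintic smoothstep over `ramp_time`, then held until the kinetic/internal
#' energy ratio falls below `ke_ratio_tol` (quasi-static acceptance). Light
#' mass-proportional damping (`damping`, 1/s; default `25 / ramp_time`)
#' dissipates transients. `mass_scaling` multiplies the tissue density to
#' enlarge the stable time step in quasi-static runs; the energy-ratio check
#' guards its validity.
#'
#' @param dt_factor Multiplicative safety factor on the critical time step.
#' @param ramp_time Moment ramp duration, s.
#' @param settle_factor Maximum additional hold time, as a multiple of
#'   `ramp_time`, before a non-quasi-static error is raised.
#' @param damping Mass-proportional damping coefficient (1/s);
#'   `NULL` selects `25 / ramp_time`.
#' @param ke_ratio_tol Kinetic/internal energy ratio below which the held
#'   state is accepted (default 1%).
#' @param n_increments Number of moment increments at which the
#'   moment-rotation (ROM) curve is sampled.
#' @param wavespeed `"approx"` (five fiber directions, the production path)
#'   or `"theoretical"` (in-run dense direction maximization for audit runs).
#' @param theoretical_grid Angular grid resolution per angle when
#'   `wavespeed = "theoretical"`.
#' @param mass_scaling Density multiplier for quasi-static mass scaling.
#' @param record_every Record the time-series trace every this many steps.
#' @param max_steps Hard step limit.
#' @param ke_blowup_factor Kinetic energy above this multiple of the external
#'   work raises an instability error.
#' @param verbose Print progress every 2000 steps.
#' @return Object of class `ivd_solver_controls`.
#' @export
solver_controls <- function(dt_factor = 0.9, ramp_time = 0.05,
                            settle_factor = 2, damping = NULL,
                            ke_ratio_tol = 0.01, n_increments = 10,
                            wavespeed = c("approx", "theoretical"),
                            theoretical_grid = 24L, mass_scaling = 1,
                            record_every = 25L, max_steps = 2e6,
                            ke_blowup_factor = 100, verbose = FALSE) {
  wavespeed <- match.arg(wavespeed)
  if (dt_factor <= 0) stop("dt_factor must be positive")
  if (is.null(damping)) damping <- 25 / ramp_time
  structure(list(dt_factor = dt_factor, ramp_time = ramp_time,
                 settle_factor = settle_factor, damping = damping,
                 ke_ratio_tol = ke_ratio_tol, n_increments = n_increments,
                 wavespeed = wavespeed, theoretical_grid = theoretical_grid,
                 mass_scaling = mass_scaling, record_every = record_every,
                 max_steps = max_steps, ke_blowup_factor = ke_blowup_factor,
                 verbose = verbose),
            class = "ivd_solver_controls")
}

#' Row-sum lumped nodal masses
#'
#' Distributes each element's mass equally to its four nodes
#' (volume/4 lumping); total mass is conserved exactly.
#'
#' @param mesh An `ivd_mesh` (coordinates in mm).
#' @param rho0 Reference density, kg/m^3 (scalar or per element).
#' @return Nodal mass vector, kg.
#' @export
lumped_mass <- function(mesh, rho0 = 1000) {
  Vm3 <- mesh$volume * 1e-9 # mm^3 -> m^3
  me <- rep(rho0, length.out = length(Vm3)) * Vm3 / 4
  nid <- as.integer(mesh$tets)
  m <- numeric(nrow(mesh$nodes))
  acc <- rowsum(rep(me, 4), nid)
  m[as.integer(rownames(acc))] <- acc[, 1]
  m
}

# exponential map / Rodrigues rotation from a rotation vector
.rot_exp <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-14) return(diag(3) + .skew(w))
  K <- .skew(w / th)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.skew <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

.rot_log <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(max(ct, -1), 1)
  th <- acos(ct)
  if (th < 1e-12) {
    return(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2)
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(th))
  th * ax
}

#' Rotation angle about a load axis
#'
#' Extracts the range-of-motion angle: the component of the rotation vector
#' of the cranial body along the load axis, in degrees.
#'
#' @param rotation A 3x3 rotation matrix, or an `ivd_result` (uses the final
#'   cranial rotation).
#' @param axis Unit load axis.
#' @return Signed angle in degrees.
#' @examples
#' rom_angle(diag(3), c(1, 0, 0))  # 0
#' @export
rom_angle <- function(rotation, axis) {
  if (inherits(rotation, "ivd_result")) rotation <- rotation$cranial_rotation
  w <- .rot_log(rotation)
  sum(w * axis / sqrt(sum(axis^2))) * 180 / pi
}

# --- assembly -------------------------------------------------------------

# static geometric data shared by internal_forces() and run_explicit();
# all lengths in meters
.assembly_setup <- function(mesh, np, af) {
  X <- mesh$nodes * 1e-3
  tets <- mesh$tets
  E <- nrow(tets)
  d1 <- X[tets[, 2], , drop = FALSE] - X[tets[, 1], , drop = FALSE]
  d2 <- X[tets[, 3], , drop = FALSE] - X[tets[, 1], , drop = FALSE]
  d3 <- X[tets[, 4], , drop = FALSE] - X[tets[, 1], , drop = FALSE]
  # D columns are the reference edges; cbind(d1, d2, d3) is already the
  # column-major E x 9 storage. H = D^{-1}.
  D <- cbind(d1, d2, d3)
  detD <- batch_det9(D)
  if (any(detD <= 0)) stop("element inversion in reference configuration")
  H <- cbind(
    D[, 5] * D[, 9] - D[, 8] * D[, 6], -(D[, 2] * D[, 9] - D[, 8] * D[, 3]),
    D[, 2] * D[, 6] - D[, 5] * D[, 3], -(D[, 4] * D[, 9] - D[, 7] * D[, 6]),
    D[, 1] * D[, 9] - D[, 7] * D[, 3], -(D[, 1] * D[, 6] - D[, 4] * D[, 3]),
    D[, 4] * D[, 8] - D[, 7] * D[, 5], -(D[, 1] * D[, 8] - D[, 7] * D[, 2]),
    D[, 1] * D[, 5] - D[, 4] * D[, 2]) / detD
  Ht <- H[, c(1, 4, 7, 2, 5, 8, 3, 6, 9), drop = FALSE]
  V0 <- detD / 6
  af_el <- which(mesh$region == "AF")
  np_el <- which(mesh$region == "NP")
  M1 <- mesh$M1[af_el, , drop = FALSE]
  M2 <- mesh$M2[af_el, , drop = FALSE]
  if (length(af_el) && any(!is.finite(M1)))
    stop("AF elements lack fiber directions; run assign_fiber_frames()")
  list(X = X, tets = tets, E = E, H = H, Ht = Ht, V0 = V0,
       af_el = af_el, np_el = np_el, M1 = M1, M2 = M2,
       pars_af = mat_pars(af), pars_np = mat_pars(np),
       nid = as.integer(tets))
}

# deformation gradients (E x 9) from current nodal positions (m)
.batch_F <- function(setup, x) {
  t1 <- setup$tets[, 1]
  e1 <- x[setup$tets[, 2], , drop = FALSE] - x[t1, , drop = FALSE]
  e2 <- x[setup$tets[, 3], , drop = FALSE] - x[t1, , drop = FALSE]
  e3 <- x[setup$tets[, 4], , drop = FALSE] - x[t1, , drop = FALSE]
  mat3_mul_batch(cbind(e1, e2, e3), setup$H)
}

# stress state of every element; returns kinematics, PK2, energies split by
# region but indexed over the full element list
.batch_state <- function(setup, Fm) {
  E <- setup$E
  S <- matrix(0, E, 6)
  psi <- matrix(0, E, 3) # iso, vol, aniso
  kin <- batch_kin(Fm)
  if (any(kin$J <= 0)) {
    bad <- which(kin$J <= 0)[1]
    stop(errorCondition(
      sprintf("element inversion: J = %g in element %d", kin$J[bad], bad),
      class = c("ivdfem_inversion", "ivdfem_instability", "error", "condition")))
  }
  sub_kin <- function(k, el) lapply(k, function(v) {
    if (is.matrix(v)) v[el, , drop = FALSE] else v[el]
  })
  st_af <- st_np <- NULL
  if (length(setup$af_el)) {
    ka <- sub_kin(kin, setup$af_el)
    st_af <- batch_stress(ka, setup$pars_af, setup$M1, setup$M2)
    S[setup$af_el, ] <- st_af$S
    psi[setup$af_el, ] <- cbind(st_af$psi_iso, st_af$psi_vol, st_af$psi_aniso)
    st_af$kin <- ka
  }
  if (length(setup$np_el)) {
    kn <- sub_kin(kin, setup$np_el)
    st_np <- batch_stress(kn, setup$pars_np)
    S[setup$np_el, ] <- st_np$S
    psi[setup$np_el, ] <- cbind(st_np$psi_iso, st_np$psi_vol, 0)
    st_np$kin <- kn
  }
  list(kin = kin, S = S, psi = psi, st_af = st_af, st_np = st_np)
}

# nodal internal forces (N) from PK2 stresses; restoring sign convention
.batch_forces <- function(setup, Fm, S) {
  P <- mat3_mul_batch(Fm, sym6_to9(S)) # first Piola-Kirchhoff
  G <- mat3_mul_batch(P, setup$Ht) * setup$V0 # col k = -force on node k+1
  f2 <- -G[, 1:3, drop = FALSE]
  f3 <- -G[, 4:6, drop = FALSE]
  f4 <- -G[, 7:9, drop = FALSE]
  f1 <- -(f2 + f3 + f4)
  acc <- rowsum(rbind(f1, f2, f3, f4), setup$nid)
  f <- matrix(0, nrow(setup$X), 3)
  f[as.integer(rownames(acc)), ] <- acc
  f
}

#' Assembled internal nodal forces
#'
#' Assembles the restoring internal force vector (the negative gradient of
#' total strain energy with respect to nodal positions) over constant-gradient
#' tetrahedra.
#'
#' @param mesh An `ivd_mesh` (mm).
#' @param displacement N x 3 nodal displacement matrix in mm.
#' @param np,af Materials for the two regions.
#' @return N x 3 matrix of nodal forces in N.
#' @export
internal_forces <- function(mesh, displacement, np, af) {
  setup <- .assembly_setup(mesh, np, af)
  x <- setup$X + displacement * 1e-3
  Fm <- .batch_F(setup, x)
  stt <- .batch_state(setup, Fm)
  .batch_forces(setup, Fm, stt$S)
}

# per-element max wave speed for the adaptive time step
.batch_vmax <- function(setup, state, controls, rho_scale, dirsAF) {
  E <- setup$E
  v2 <- numeric(E)
  if (length(setup$af_el)) {
    st <- state$st_af
    sig <- batch_cauchy(st$kin$F, st$S, st$kin$J)
    if (controls$wavespeed == "approx") {
      vbest <- rep(-Inf, length(setup$af_el))
      Fm <- st$kin$F
      for (D in dirsAF) {
        # convect the reference candidate to the current configuration
        n1 <- Fm[, 1] * D[, 1] + Fm[, 4] * D[, 2] + Fm[, 7] * D[, 3]
        n2 <- Fm[, 2] * D[, 1] + Fm[, 5] * D[, 2] + Fm[, 8] * D[, 3]
        n3 <- Fm[, 3] * D[, 1] + Fm[, 6] * D[, 2] + Fm[, 9] * D[, 3]
        nn <- sqrt(n1^2 + n2^2 + n3^2)
        N <- cbind(n1 / nn, n2 / nn, n3 / nn, deparse.level = 0)
        vv <- batch_v2_dir(st$kin, st, setup$pars_af, sig, N,
                           setup$M1, setup$M2)
        vbest <- pmax(vbest, vv)
      }
    } else {
      ng <- controls$theoretical_grid
      ang <- seq(0, pi, length.out = ng + 1L)[seq_len(ng)]
      G <- expand.grid(phi = ang, theta = ang)
      vbest <- rep(-Inf, length(setup$af_el))
      nE <- length(setup$af_el)
      for (gi in seq_len(nrow(G))) {
        n <- .n_from_angles(G$phi[gi], G$theta[gi])
        N <- matrix(n, nE, 3, byrow = TRUE)
        vv <- batch_v2_dir(st$kin, st, setup$pars_af, sig, N,
                           setup$M1, setup$M2)
        vbest <- pmax(vbest, vv)
      }
    }
    v2[setup$af_el] <- vbest
  }
  if (length(setup$np_el)) {
    st <- state$st_np
    v2[setup$np_el] <- batch_v2_principal_max(st$kin, st, setup$pars_np)
  }
  if (any(v2 <= 0)) {
    bad <- which(v2 <= 0)[1]
    stop(errorCondition(
      sprintf("material instability: non-positive wave speed in element %d", bad),
      class = c("ivdfem_instability", "error", "condition")))
  }
  sqrt(v2 / rho_scale)
}

# C2 quintic smoothstep
.smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x^3 * (10 - 15 * x + 6 * x^2)
}

#' Run an explicit quasi-static simulation
#'
#' Central-difference (symplectic Euler) time integration of the spinal
#' segment under a ramped pure moment. The moment rises with a C2 smoothstep
#' over the ramp time and is then held until the kinetic/internal energy
#' ratio drops below the quasi-static tolerance. Every step, the stable time
#' increment is recomputed per element from the current deformation state:
#' the five-fiber-direction wave-speed approximation for annulus elements and
#' the principal-direction speed for nucleus elements, combined with the
#' characteristic length through the critical-time-step formula; the global
#' step is the minimum over elements times `dt_factor`.
#'
#' The disc interface node layers are tied rigidly to the two vertebra
#' bodies: the cranial body carries the applied torque (free 6-DOF), the
#' caudal body may only translate in the moment plane.
#'
#' Raised conditions: `ivdfem_inversion` (element inversion),
#' `ivdfem_instability` (energy blow-up, non-finite state, or loss of
#' rank-one convexity), `ivdfem_not_converged` (quasi-static ratio not met
#' within the settle window).
#'
#' @param mesh An `ivd_mesh` with fiber frames.
#' @param np,af Materials ([np_material()], [af_material()]).
#' @param load An [load_case()].
#' @param controls An [solver_controls()].
#' @return Object of class `ivd_result`; see [tidy.ivd_result()],
#'   [glance.ivd_result()] and [autoplot.ivd_result()]. Contains the ROM
#'   curve (`rom_curve`), a time-series `trace`, per-element peak-load fields
#'   (`elements`), the energy ledger (`energy`), the cranial rotation matrix
#'   and displacement fields.
#' @export
run_explicit <- function(mesh, np, af, load, controls = solver_controls()) {
  stopifnot(inherits(mesh, "ivd_mesh"), inherits(load, "ivd_load_case"),
            inherits(controls, "ivd_solver_controls"))
  setup <- .assembly_setup(mesh, np, af)
  Nn <- nrow(setup$X)
  rho_af <- af$rho0 * controls$mass_scaling
  rho_np <- np$rho0 * controls$mass_scaling
  rho_el <- ifelse(mesh$region == "AF", rho_af, rho_np)
  mass <- lumped_mass(mesh, rho_el)
  lc_m <- mesh$l_c * 1e-3
  # per-element density used inside the wave-speed formulas is uniform per
  # region; v = sqrt(v2_ref / scale) folds the mass scaling in
  rho_scale <- controls$mass_scaling

  # five approximation directions per AF element (constant reference vectors)
  dirsAF <- NULL
  if (length(setup$af_el)) {
    M1 <- setup$M1; M2 <- setup$M2
    cr <- cbind(M1[, 2] * M2[, 3] - M1[, 3] * M2[, 2],
                M1[, 3] * M2[, 1] - M1[, 1] * M2[, 3],
                M1[, 1] * M2[, 2] - M1[, 2] * M2[, 1])
    nrmz <- function(A) A / sqrt(rowSums(A^2))
    dirsAF <- list(M1, M2, nrmz(M1 + M2), nrmz(M1 - M2), nrmz(cr))
  }

  # rigid bodies ------------------------------------------------------------
  centroid <- colSums(setup$X[setup$tets[, 1], ] + setup$X[setup$tets[, 2], ] +
                        setup$X[setup$tets[, 3], ] + setup$X[setup$tets[, 4], ]) /
    (4 * setup$E)
  h_mean <- diff(range(setup$X[, 3]))
  slab_mass <- 1000 * controls$mass_scaling * sum(setup$V0) * (5e-3 / h_mean)
  make_body <- function(nodes_idx, mode) {
    Xn <- setup$X[nodes_idx, , drop = FALSE]
    mn <- mass[nodes_idx]
    mb <- slab_mass + sum(mn)
    share <- mn + slab_mass / length(nodes_idx)
    r <- sweep(Xn, 2, centroid)
    I0 <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3)
      I0[i, j] <- sum(share * ((i == j) * rowSums(r^2) - r[, i] * r[, j]))
    I0 <- I0 + diag(3) * 1e-3 * max(diag(I0))
    list(nodes = nodes_idx, ref0 = centroid, r0 = r, mass = mb, I0 = I0,
         mode = mode, xc = centroid, vc = c(0, 0, 0), R = diag(3),
         om = c(0, 0, 0))
  }
  cran <- make_body(mesh$cranial_nodes, "free")
  caud <- make_body(mesh$caudal_nodes, "in_plane")
  tied <- c(cran$nodes, caud$nodes)
  free <- setdiff(seq_len(Nn), tied)
  plane_proj <- diag(3) - load$axis %o% load$axis

  x <- setup$X
  v <- matrix(0, Nn, 3)
  cdamp <- controls$damping
  t_now <- 0
  W_ext <- 0; E_damp <- 0
  Mgrid <- seq(0, load$moment, length.out = controls$n_increments + 1L)[-1]
  rom_m <- numeric(0); rom_th <- numeric(0)
  next_inc <- 1L
  trace <- list()
  t_end <- controls$ramp_time * (1 + controls$settle_factor)
  step <- 0L
  dt_hist_min <- Inf; dt_hist_max <- 0
  status <- "running"
  E_int <- 0; KE <- 0

  repeat {
    step <- step + 1L
    if (step > controls$max_steps) {
      stop(errorCondition(
        sprintf("quasi-static state not reached within %d steps", controls$max_steps),
        class = c("ivdfem_not_converged", "error", "condition")))
    }
    Fm <- .batch_F(setup, x)
    state <- .batch_state(setup, Fm)
    f <- .batch_forces(setup, Fm, state$S)
    E_int <- sum(setup$V0 * rowSums(state$psi))

    vmax <- .batch_vmax(setup, state, controls, rho_scale, dirsAF)
    dt <- controls$dt_factor * min(lc_m / vmax)
    dt_hist_min <- min(dt_hist_min, dt); dt_hist_max <- max(dt_hist_max, dt)

    mom <- load$moment * .smoothstep(t_now / controls$ramp_time)
    torque <- mom * load$axis

    # free tissue nodes: symplectic Euler with mass-proportional damping
    a <- f[free, , drop = FALSE] / mass[free]
    vf <- v[free, , drop = FALSE]
    vf <- (vf + a * dt) / (1 + cdamp * dt)
    v[free, ] <- vf
    x[free, ] <- x[free, , drop = FALSE] + vf * dt

    # rigid bodies
    upd_body <- function(b, Tq) {
      idx <- b$nodes
      fb <- colSums(f[idx, , drop = FALSE])
      r1 <- x[idx, 1] - b$xc[1]
      r2 <- x[idx, 2] - b$xc[2]
      r3 <- x[idx, 3] - b$xc[3]
      tq <- Tq + c(sum(r2 * f[idx, 3] - r3 * f[idx, 2]),
                   sum(r3 * f[idx, 1] - r1 * f[idx, 3]),
                   sum(r1 * f[idx, 2] - r2 * f[idx, 1]))
      if (b$mode == "free") {
        It <- b$R %*% b$I0 %*% t(b$R)
        al <- solve(It, tq - .skew(b$om) %*% (It %*% b$om))
        b$om <- (b$om + as.numeric(al) * dt) / (1 + cdamp * dt)
        b$R <- .rot_exp(b$om * dt) %*% b$R
        acc <- fb / b$mass
        b$vc <- (b$vc + acc * dt) / (1 + cdamp * dt)
        b$xc <- b$xc + b$vc * dt
      } else { # translate in the moment plane only
        acc <- as.numeric(plane_proj %*% (fb / b$mass))
        b$vc <- (b$vc + acc * dt) / (1 + cdamp * dt)
        b$vc <- as.numeric(plane_proj %*% b$vc)
        b$xc <- b$xc + b$vc * dt
      }
      rR <- b$r0 %*% t(b$R)
      xn <- cbind(rR[, 1] + b$xc[1], rR[, 2] + b$xc[2], rR[, 3] + b$xc[3],
                  deparse.level = 0)
      x[idx, ] <<- xn
      # tied node velocity: v_c + omega x (x_n - x_c)
      om <- b$om
      v[idx, ] <<- cbind(b$vc[1] + om[2] * rR[, 3] - om[3] * rR[, 2],
                         b$vc[2] + om[3] * rR[, 1] - om[1] * rR[, 3],
                         b$vc[3] + om[1] * rR[, 2] - om[2] * rR[, 1],
                         deparse.level = 0)
      b
    }
    cran <- upd_body(cran, torque)
    caud <- upd_body(caud, c(0, 0, 0))

    # energy ledger
    W_ext <- W_ext + sum(torque * cran$om) * dt
    pdamp <- cdamp * (sum(mass[free] * rowSums(v[free, , drop = FALSE]^2)) +
                        cran$mass * sum(cran$vc^2) +
                        sum(cran$om * (cran$R %*% cran$I0 %*% t(cran$R) %*% cran$om)) +
                        caud$mass * sum(caud$vc^2))
    E_damp <- E_damp + pdamp * dt
    KE <- 0.5 * (sum(mass[free] * rowSums(v[free, , drop = FALSE]^2)) +
                   cran$mass * sum(cran$vc^2) +
                   sum(cran$om * (cran$R %*% cran$I0 %*% t(cran$R) %*% cran$om)) +
                   caud$mass * sum(caud$vc^2))
    t_now <- t_now + dt

    if (!all(is.finite(x)) || !is.finite(KE) ||
        (t_now > 0.2 * controls$ramp_time &&
           KE > controls$ke_blowup_factor * max(abs(W_ext), 1e-9))) {
      stop(errorCondition(
        sprintf("instability detected at step %d (t = %.4g s): kinetic energy blow-up", step, t_now),
        class = c("ivdfem_instability", "error", "condition")))
    }

    theta <- rom_angle(cran$R, load$axis)
    while (next_inc <= length(Mgrid) && mom >= Mgrid[next_inc] - 1e-12) {
      rom_m <- c(rom_m, Mgrid[next_inc]); rom_th <- c(rom_th, theta)
      next_inc <- next_inc + 1L
    }
    if (step %% controls$record_every == 0L) {
      trace[[length(trace) + 1L]] <-
        c(t_now, dt, mom, theta, KE, E_int, W_ext, E_damp)
    }
    if (controls$verbose && step %% 2000L == 0L)
      message(sprintf("step %d t=%.4gs dt=%.3g mom=%.3g rom=%.3g KE/Ei=%.3g",
                      step, t_now, dt, mom, theta, KE / max(E_int, 1e-12)))

    if (t_now >= controls$ramp_time && KE <= controls$ke_ratio_tol * E_int) {
      status <- "converged"
      break
    }
    if (t_now >= t_end) {
      stop(errorCondition(
        sprintf("quasi-static ratio %.3g not below %.3g within the settle window",
                KE / max(E_int, 1e-12), controls$ke_ratio_tol),
        class = c("ivdfem_not_converged", "error", "condition")))
    }
  }

  # final state fields at peak load
  Fm <- .batch_F(setup, x)
  state <- .batch_state(setup, Fm)
  sigma <- matrix(0, setup$E, 6)
  if (length(setup$af_el))
    sigma[setup$af_el, ] <- batch_cauchy(state$st_af$kin$F, state$st_af$S,
                                         state$st_af$kin$J)
  if (length(setup$np_el))
    sigma[setup$np_el, ] <- batch_cauchy(state$st_np$kin$F, state$st_np$S,
                                         state$st_np$kin$J)
  press <- -(sigma[, 1] + sigma[, 2] + sigma[, 3]) / 3
  theta <- rom_angle(cran$R, load$axis)
  rom_m <- c(rom_m, load$moment); rom_th <- c(rom_th, theta)
  keep <- !duplicated(rom_m, fromLast = TRUE)
  rom_curve <- tibble::tibble(moment_nm = c(0, rom_m[keep]),
                              rom_deg = c(0, rom_th[keep]))
  tr <- if (length(trace)) {
    m <- do.call(rbind, trace)
    tibble::tibble(time_s = m[, 1], dt_s = m[, 2], moment_nm = m[, 3],
                   rom_deg = m[, 4], e_kin = m[, 5], e_int = m[, 6],
                   w_ext = m[, 7], e_damp = m[, 8])
  } else tibble::tibble()
  closure <- abs(W_ext - (E_int + KE + E_damp)) / max(abs(W_ext), 1e-12)

  structure(list(
    rom_curve = rom_curve,
    trace = tr,
    elements = tibble::tibble(
      element = seq_len(setup$E), region = mesh$region,
      J = state$kin$J, pressure_pa = press,
      psi_iso = state$psi[, 1], psi_vol = state$psi[, 2],
      psi_aniso = state$psi[, 3]),
    F_peak = Fm, sigma_peak = sigma,
    nodes_final_mm = x * 1e3,
    cranial_rotation = cran$R,
    peak_rom_deg = theta,
    energy = list(W_ext = W_ext, E_int = E_int, E_kin = KE,
                  E_damp = E_damp, closure = closure),
    dt_range = c(dt_hist_min, dt_hist_max),
    n_steps = step, time_s = t_now, status = status,
    load = load, controls = controls, mesh = mesh,
    materials = list(np = np, af = af)
  ), class = "ivd_result")
}

#' @export
print.ivd_result <- function(x, ...) {
  cat(sprintf(
    "<ivd_result> %s %.3g N*m: ROM %.3f deg, %d steps (dt %.3g..%.3g s), KE/Ei %.2g%%, ledger closure %.2g%%\n",
    x$load$name, x$load$moment, x$peak_rom_deg, x$n_steps,
    x$dt_range[1], x$dt_range[2],
    100 * x$energy$E_kin / max(x$energy$E_int, 1e-12),
    100 * x$energy$closure))
  invisible(x)
}
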