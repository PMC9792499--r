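# Pointwise constitutive model: kinematics, energies, stresses, tangents.

test_that("kinematic decomposition matches closed forms", {
  st <- decompose_kinematics(diag(3))
  expect_equal(st$J, 1)
  expect_equal(st$C_bar, diag(3))
  expect_equal(st$I1_bar, 3)
  expect_equal(st$I2_bar, 3)

  st <- decompose_kinematics(2 * diag(3))
  expect_equal(st$J, 8)
  expect_equal(st$F_bar, diag(3))
  expect_equal(st$C_bar, diag(3))

  st <- decompose_kinematics(diag(c(2, 1, 1)))
  expect_equal(st$J, 2)
  expect_equal(st$C_bar, 2^(-2 / 3) * diag(c(4, 1, 1)))
  expect_equal(st$I1_bar, 6 * 2^(-2 / 3), tolerance = 1e-12)

  expect_error(decompose_kinematics(diag(c(-1, 1, 1))), "det\\(F\\)")
})

test_that("unimodularity and invariant floors hold on random states", {
  set.seed(11)
  for (i in 1:200) {
    st <- decompose_kinematics(random_F(0.3))
    expect_lt(abs(det(st$C_bar) - 1), 1e-12)
    expect_gte(st$I1_bar, 3 - 1e-12)
    expect_gte(st$I2_bar, 3 - 1e-12)
  }
})

test_that("macaulay bracket clamps at zero", {
  expect_identical(macaulay(c(-1, 0, 2)), c(0, 0, 2))
})

test_that("NP energy matches hand-evaluated examples", {
  np <- table1_np()
  e <- energy_np(decompose_kinematics(diag(3)), np)
  expect_equal(e$psi_iso, 0)
  expect_equal(e$psi_vol, 0)
  expect_equal(e$psi_aniso, 0)

  # uniaxial stretch 2: I1b = 3.7798, I2b = 3.5717, J = 2 (values in Pa)
  e <- energy_np(decompose_kinematics(diag(c(2, 1, 1))), np)
  expect_equal(e$psi_iso, 110.72, tolerance = 1e-4)
  expect_equal(e$psi_vol, 14950)

  # isochoric simple shear, amount 0.5: I1b = I2b = 3.25
  Fs <- diag(3); Fs[1, 2] <- 0.5
  e <- energy_np(decompose_kinematics(Fs), np)
  expect_equal(e$psi_iso, (np$b10 + np$b01) * 0.25, tolerance = 1e-12)
  expect_equal(e$psi_vol, 0)
})

test_that("AF fiber energy engages in tension only", {
  af <- table1_af()
  fb <- fiber_pair_from_angle(30)
  e <- energy_af(decompose_kinematics(diag(3)), af, fb)
  expect_equal(e$psi_aniso, 0)
  expect_equal(e$IM1_bar, 1)
  expect_equal(e$IM2_bar, 1)

  # isochoric uniaxial stretch 1.2 along e1: IM = 1.44*0.75 + 0.25/1.2
  Fs <- diag(c(1.2, 1.2^-0.5, 1.2^-0.5))
  e <- energy_af(decompose_kinematics(Fs), af, fb)
  IM <- 1.44 * 0.75 + 0.25 / 1.2
  expect_equal(e$IM1_bar, IM, tolerance = 1e-12)
  expect_equal(e$IM2_bar, IM, tolerance = 1e-12)
  expect_equal(e$psi_aniso,
               2 * (af$a1 / af$a2) * (exp(af$a2 * (IM - 1)^2) - 1),
               tolerance = 1e-12)

  # isochoric contraction: both fiber invariants < 1, Macaulay clamp
  Fc <- diag(c(0.9, 0.9^-0.5, 0.9^-0.5))
  e <- energy_af(decompose_kinematics(Fc), af, fb)
  expect_lt(e$IM1_bar, 1)
  expect_equal(e$psi_aniso, 0)
})

test_that("stress-free reference and dilation closed form", {
  np <- table1_np(); af <- table1_af()
  fb <- fiber_pair_from_angle(30)
  expect_equal(norm(pk2_stress(decompose_kinematics(diag(3)), np), "F"), 0)
  expect_equal(norm(pk2_stress(decompose_kinematics(diag(3)), af, fb), "F"), 0)

  # pure dilation 1.1: S = k (J-1) J C^-1, sigma = k (J-1) I
  st <- decompose_kinematics(1.1 * diag(3))
  S <- pk2_stress(st, np)
  expect_equal(S, np$k * (1.331 - 1) * 1.331 / 1.21 * diag(3),
               tolerance = 1e-10)
  sg <- cauchy_stress(S, st$F)
  expect_equal(sg, np$k * 0.331 * diag(3), tolerance = 1e-10)
})

test_that("cauchy push-forward basics", {
  S <- matrix(c(3, 1, 0, 1, -2, 0.5, 0, 0.5, 1), 3, 3)
  expect_equal(cauchy_stress(S, diag(3)), S)
  set.seed(3)
  w <- rnorm(3)
  Q <- ivdfem:::.rot_exp(w)
  expect_equal(cauchy_stress(S, Q), Q %*% S %*% t(Q), tolerance = 1e-12)
})

test_that("analytic PK2 matches the finite-difference oracle on 100 states", {
  np <- table1_np(); af <- table1_af()
  fb <- fiber_pair_from_angle(30)
  set.seed(21)
  worst <- 0
  for (i in 1:100) {
    F <- random_F()
    st <- decompose_kinematics(F)
    mat <- if (i %% 2 == 0) np else af
    fbi <- if (i %% 2 == 0) NULL else fb
    Sa <- pk2_stress(st, mat, fbi)
    Sf <- fd_pk2(st$C, mat, fbi)
    worst <- max(worst, max(abs(Sa - Sf)) / max(abs(Sa), 1))
  }
  expect_lt(worst, 1e-6)
})

test_that("analytic elasticity tensors match finite differences and hold symmetries", {
  np <- table1_np(); af <- table1_af()
  fb <- fiber_pair_from_angle(30)
  set.seed(22)
  for (i in 1:12) {
    F <- random_F(0.12)
    st <- decompose_kinematics(F)
    mat <- if (i %% 2 == 0) np else af
    fbi <- if (i %% 2 == 0) NULL else fb
    eb <- elasticity_tensors(st, mat, fbi)
    Cfd <- fd_cmat(st$C, mat, fbi)
    expect_lt(max(abs(eb$C_mat - Cfd)) / max(abs(eb$C_mat)), 1e-5)
    # minor and major symmetries
    expect_lt(max(abs(eb$C_mat - aperm(eb$C_mat, c(2, 1, 3, 4)))) /
                max(abs(eb$C_mat)), 1e-8)
    expect_lt(max(abs(eb$C_mat - aperm(eb$C_mat, c(3, 4, 1, 2)))) /
                max(abs(eb$C_mat)), 1e-8)
  }
})

test_that("spatial tensor linearizes to isotropic elasticity at the NP reference", {
  np <- table1_np()
  st <- decompose_kinematics(diag(3))
  eb <- elasticity_tensors(st, np)
  mu <- 2 * (np$b10 + np$b01)
  iso <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    iso[i, j, k, l] <- (np$k - 2 * mu / 3) * (i == j) * (k == l) +
      mu * ((i == k) * (j == l) + (i == l) * (j == k))
  expect_equal(eb$c_spat, iso, tolerance = 1e-10)
  # push-forward at identity is the identity map on the tensor
  expect_equal(eb$c_spat, eb$C_mat)
})

test_that("energies are objective, fiber-symmetric and non-negative", {
  af <- table1_af()
  fb <- fiber_pair_from_angle(30)
  fb_swap <- fiber_pair(fb$M2, fb$M1)
  set.seed(23)
  for (i in 1:300) {
    F <- random_F(0.2)
    Q <- ivdfem:::.rot_exp(rnorm(3))
    st <- decompose_kinematics(F)
    stQ <- decompose_kinematics(Q %*% F)
    e <- energy_af(st, af, fb)
    eQ <- energy_af(stQ, af, fb)
    if (!is.finite(e$psi_aniso)) next # exponential overflow at extreme stretch
    for (fld in c("psi_iso", "psi_vol", "psi_aniso")) {
      expect_lt(abs(e[[fld]] - eQ[[fld]]) / max(abs(e[[fld]]), 1e-10), 1e-10)
      expect_gte(e[[fld]], 0)
    }
    es <- energy_af(st, af, fb_swap)
    expect_equal(es$psi_aniso, e$psi_aniso, tolerance = 1e-12)
  }
})

test_that("fiber compression contributes no stress", {
  af <- table1_af()
  fb <- fiber_pair_from_angle(30)
  # contraction keeps both fiber families slack; matrix-only reference
  mat_only <- af_material(af$c10, af$c01, a1 = 1e-12, a2 = af$a2, k = af$k,
                          units = "Pa")
  set.seed(5)
  for (i in 1:20) {
    lam <- runif(1, 0.85, 0.97)
    Fc <- diag(c(lam, lam^-0.45, lam^-0.45)) # mild perturbation around slack
    st <- decompose_kinematics(Fc)
    e <- energy_af(st, af, fb)
    if (e$IM1_bar <= 1 && e$IM2_bar <= 1) {
      expect_equal(e$psi_aniso, 0)
      expect_equal(pk2_stress(st, af, fb), pk2_stress(st, mat_only, fb),
                   tolerance = 1e-9)
    }
  }
})

test_that("pressure sign convention is compression-positive", {
  expect_equal(pressure(-5 * diag(3)), 5)
  sh <- matrix(c(0, 1, 0, 1, 0, 2, 0, 2, 0), 3, 3)
  expect_equal(pressure(sh), 0)
  expect_equal(pressure(9896.9 * diag(3)), -9896.9)
})

test_that("bulk modulus reconstruction reproduces the shipped presets", {
  expect_equal(bulk_from_poisson(0.12, 0.03, 0.495), 29.9, tolerance = 5e-4)
  expect_equal(bulk_from_poisson(0.18, 0.045, 0.45), 4.35, tolerance = 5e-4)
  expect_equal(bulk_from_poisson(1, 0.5, 0), 2 * 3 / 3)
  expect_error(bulk_from_poisson(1, 0, 0.5), "incompressible")
})

test_that("material constructors validate and convert units", {
  np <- np_material(0.12, 0.03, 29.9)
  expect_equal(np$b10, 120) # Pa
  expect_error(np_material(-1, 0, 1), "b10")
  expect_error(af_material(0.1, 0, 1, 100, 4, phi = 95), "phi")
  af <- material_preset("af_table3")
  expect_equal(af$a2, 151)
  expect_equal(af$k, 170e3)
})
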