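# Synthetic segment generation, fiber frames, characteristic lengths, mesh I/O.

test_that("generated segments are watertight with both regions populated", {
  mesh <- coarse_mesh()
  expect_true(all(mesh$volume > 0))
  expect_true(all(c("AF", "NP") %in% mesh$region))
  expect_equal(sum(mesh$region == "AF") + sum(mesh$region == "NP"),
               nrow(mesh$tets))
  expect_gt(length(mesh$cranial_nodes), 0)
  expect_gt(length(mesh$caudal_nodes), 0)
  expect_length(intersect(mesh$cranial_nodes, mesh$caudal_nodes), 0)
})

test_that("mesh volume converges to the analytic volume", {
  sp <- segment_spec(element_size = 2)
  mesh <- generate_segment(sp)
  expect_lt(abs(sum(mesh$volume) - segment_volume(sp)) / segment_volume(sp),
            0.02)
})

test_that("generation is deterministic for fixed spec and seed", {
  sp <- segment_spec(element_size = 6)
  a <- generate_segment(sp, seed = 7)
  b <- generate_segment(sp, seed = 7)
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$tets, b$tets)
  expect_identical(a$region, b$region)
})

test_that("degeneration presets reduce height and add wedge/skew", {
  none <- segment_spec(preset = "none")
  sev <- segment_spec(preset = "severe")
  expect_lt(min(sev$h_ant, sev$h_post), min(none$h_ant, none$h_post))
  expect_gt(sev$skew, 0)
  expect_gt(abs(sev$h_ant - sev$h_post), abs(none$h_ant - none$h_post))
  m <- generate_segment(segment_spec(element_size = 2, preset = "severe"))
  expect_true(all(m$volume > 0))
})

test_that("too-large elements for a thin disc raise an actionable error", {
  expect_error(generate_segment(segment_spec(element_size = 9,
                                             preset = "severe")),
               "height")
})

test_that("fiber frames are unit, at the prescribed angle, tangent to the wall", {
  mesh <- coarse_mesh()
  af <- mesh$region == "AF"
  expect_equal(rowSums(mesh$M1[af, ]^2), rep(1, sum(af)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # M1 . M2 = cos(2 phi) for every element
  expect_equal(rowSums(mesh$M1[af, ] * mesh$M2[af, ]), rep(0.5, sum(af)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(is.na(mesh$M1[!af, ])))

  # tangency: for an unwedged, unskewed straight-wall disc the fiber pair sum
  # M1 + M2 is circumferential, hence perpendicular to the superellipse
  # normal at the element centroid
  sp <- segment_spec(h_ant = 10, h_post = 10, skew = 0, bulge = 0,
                     element_size = 5)
  m <- generate_segment(sp)
  afi <- which(m$region == "AF")
  idx <- afi[seq(1, length(afi), length.out = 100)]
  cen <- (m$nodes[m$tets[idx, 1], ] + m$nodes[m$tets[idx, 2], ] +
            m$nodes[m$tets[idx, 3], ] + m$nodes[m$tets[idx, 4], ]) / 4
  mm <- sp$exponent
  gx <- mm * abs(cen[, 1] / sp$r_lat)^(mm - 1) * sign(cen[, 1]) / sp$r_lat
  gy <- mm * abs(cen[, 2] / sp$r_ap)^(mm - 1) * sign(cen[, 2]) / sp$r_ap
  nrm <- cbind(gx, gy, 0)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  circ <- m$M1[idx, ] + m$M2[idx, ]
  circ <- circ / sqrt(rowSums(circ^2))
  expect_lt(max(abs(rowSums(circ * nrm))), 1e-8)
})

test_that("zero fiber angle collapses the pair and is flagged", {
  fb <- fiber_pair_from_angle(0)
  expect_true(fb$degenerate)
  expect_equal(fb$M1, fb$M2)
  m <- assign_fiber_frames(coarse_mesh(), phi = 30)
  af <- m$region == "AF"
  # angle between M1 and the transverse plane equals phi
  e2 <- m$M1[af, ] - m$M2[af, ]
  sin_phi <- sqrt(rowSums(e2^2)) / 2
  expect_equal(sin_phi, rep(sin(pi / 6), sum(af)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("characteristic length is the minimum altitude", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                 c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  m <- list(nodes = nodes, tets = matrix(1:4, 1))
  expect_equal(characteristic_length(m), sqrt(2 / 3), tolerance = 1e-12)
  # homogeneity: uniform scaling scales l_c linearly
  m2 <- list(nodes = 3.5 * nodes, tets = matrix(1:4, 1))
  expect_equal(characteristic_length(m2), 3.5 * sqrt(2 / 3),
               tolerance = 1e-12)
  # sliver: l_c below every edge length
  sl <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.4, 0.4, 0.01))
  m3 <- list(nodes = sl, tets = matrix(1:4, 1))
  edges <- as.matrix(dist(sl))
  expect_lt(characteristic_length(m3), min(edges[edges > 0]))
})

test_that("mesh files round-trip losslessly in both formats", {
  # wedged disc: the interface node sets are non-planar and must survive I/O
  mesh <- generate_segment(segment_spec(element_size = 6, preset = "moderate"))
  for (ext in c("msh", "vtk")) {
    p <- withr::local_tempfile(fileext = paste0(".", ext))
    write_mesh(mesh, p)
    m2 <- read_mesh(p)
    expect_identical(m2$tets, mesh$tets)
    expect_identical(m2$region, mesh$region)
    expect_lt(max(abs(m2$nodes - mesh$nodes)), 1e-12)
    expect_lt(max(abs(m2$M1 - mesh$M1), na.rm = TRUE), 1e-12)
    expect_identical(is.na(m2$M1), is.na(mesh$M1))
    expect_identical(is.na(m2$M2), is.na(mesh$M2))
    expect_identical(m2$cranial_nodes, mesh$cranial_nodes)
    expect_identical(m2$caudal_nodes, mesh$caudal_nodes)
  }
})

test_that("non-tetrahedral meshes are rejected", {
  p <- withr::local_tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "hex", "ASCII",
               "DATASET UNSTRUCTURED_GRID", "POINTS 8 double",
               apply(expand.grid(0:1, 0:1, 0:1), 1, paste, collapse = " "),
               "CELLS 1 9", "8 0 1 2 3 4 5 6 7", "CELL_TYPES 1", "12"), p)
  expect_error(read_mesh(p), "unsupported")
})
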