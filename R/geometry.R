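# Synthetic parametric intervertebral-disc geometry.
#
# The disc cross-section is a superellipse |x/a|^m + |y/b|^m = 1 in the
# (e1 = lateral, e2 = anterior-posterior) plane; the disc sits between a flat
# caudal endplate at z = 0 and a cranial endplate at z = h(y), where unequal
# anterior/posterior heights produce wedging, a skew offset shears the
# cranial endplate in the AP direction, and the outer wall carries a gentle
# outward mid-height bulge. The nucleus is an inner scaled superellipse.

#' Parametric spinal-segment specification
#'
#' Describes the synthetic disc geometry meshed by [generate_segment()].
#' All lengths in mm. Degeneration presets rescale the healthy geometry:
#' `"moderate"` reduces height and adds mild wedging/skew, `"severe"` halves
#' the height and applies strong wedging and skew, emulating the narrowed,
#' skewed discs of advanced degeneration.
#'
#' @param r_lat Lateral semi-axis (along e1), mm.
#' @param r_ap Anterior-posterior semi-axis (along e2), mm.
#' @param h_ant,h_post Anterior/posterior disc heights, mm (unequal values
#'   wedge the disc).
#' @param skew Shear offset of the cranial endplate along +e2, mm.
#' @param nucleus_fraction Nucleus area fraction of the cross-section,
#'   in (0, 0.8).
#' @param nucleus_offset Posterior(-)/anterior(+) offset of the nucleus
#'   centroid along e2, mm.
#' @param element_size Nominal element size, mm.
#' @param exponent Superellipse exponent (2 = ellipse; larger values square
#'   the profile off).
#' @param bulge Relative outward mid-height bulge of the annulus wall.
#' @param preset Degeneration preset: `"none"`, `"moderate"`, `"severe"`.
#'   Presets adjust heights and skew after the explicit arguments are set.
#' @return Object of class `ivd_segment_spec`.
#' @examples
#' segment_spec(preset = "severe")
#' @export
segment_spec <- function(r_lat = 25, r_ap = 17, h_ant = 11, h_post = 9,
                         skew = 0, nucleus_fraction = 0.4,
                         nucleus_offset = 0, element_size = 1.4,
                         exponent = 2.5, bulge = 0.03,
                         preset = c("none", "moderate", "severe")) {
  preset <- match.arg(preset)
  if (preset == "moderate") {
    h_ant <- 0.75 * h_ant; h_post <- 0.65 * h_post
    skew <- skew + 1
  } else if (preset == "severe") {
    h_ant <- 0.55 * h_ant; h_post <- 0.35 * h_post
    skew <- skew + 2.5
  }
  stopifnot(r_lat > 0, r_ap > 0, h_ant > 0, h_post > 0, element_size > 0,
            exponent >= 2, bulge >= 0)
  if (nucleus_fraction <= 0 || nucleus_fraction >= 0.8)
    stop("nucleus_fraction must lie in (0, 0.8)")
  structure(
    list(r_lat = r_lat, r_ap = r_ap, h_ant = h_ant, h_post = h_post,
         skew = skew, nucleus_fraction = nucleus_fraction,
         nucleus_offset = nucleus_offset, element_size = element_size,
         exponent = exponent, bulge = bulge, preset = preset),
    class = "ivd_segment_spec"
  )
}

#' @export
print.ivd_segment_spec <- function(x, ...) {
  cat(sprintf(
    "<ivd_segment_spec> preset %s: %g x %g mm, heights %g/%g mm, skew %g mm, NP %g%%, size %g mm\n",
    x$preset, x$r_lat, x$r_ap, x$h_ant, x$h_post, x$skew,
    100 * x$nucleus_fraction, x$element_size))
  invisible(x)
}

# Shirley-Chiu concentric square-to-unit-disc mapping (vectorized)
.square_to_disc <- function(u, v) {
  x <- y <- numeric(length(u))
  a_dom <- abs(u) >= abs(v) & (u != 0 | v != 0)
  b_dom <- !a_dom & v != 0
  r <- numeric(length(u)); ph <- numeric(length(u))
  r[a_dom] <- u[a_dom]
  ph[a_dom] <- (pi / 4) * (v[a_dom] / u[a_dom])
  r[b_dom] <- v[b_dom]
  ph[b_dom] <- pi / 2 - (pi / 4) * (u[b_dom] / v[b_dom])
  cbind(r * cos(ph), r * sin(ph))
}

# boundary radius of the superellipse at polar angle theta
.se_radius <- function(theta, a, b, m) {
  (abs(cos(theta) / a)^m + abs(sin(theta) / b)^m)^(-1 / m)
}

#' Analytic volume of a segment specification
#'
#' Cross-section area times mean height, corrected for the mid-height wall
#' bulge; used to check mesh convergence.
#'
#' @param spec An [segment_spec()].
#' @return Volume in mm^3.
#' @export
segment_volume <- function(spec) {
  m <- spec$exponent
  area <- 4 * spec$r_lat * spec$r_ap * gamma(1 + 1 / m)^2 / gamma(1 + 2 / m)
  h0 <- (spec$h_ant + spec$h_post) / 2
  bl <- spec$bulge
  # radial scale s(z) = 1 + 4 b z(1-z): volume factor = int s^2 dz
  area * h0 * (1 + 8 * bl / 6 + 16 * bl^2 / 30)
}

# Conforming 3-tet split of a straight prism (bottom b1,b2,b3 / top t1,t2,t3,
# t_i above b_i). Quad-face diagonals pass through the smallest global bottom
# node id of the face, which makes the choice consistent between neighboring
# prisms. Bottom ids are rotated so the smallest comes first (rotation keeps
# orientation); the split then depends only on order(b2, b3).
.prism_tets <- function(b, t) {
  r <- which.min(b) - 1L
  if (r > 0L) {
    ord <- c((r + 1L):3L, seq_len(r))
    b <- b[ord]; t <- t[ord]
  }
  if (b[2] < b[3]) {
    rbind(c(b[1], b[2], b[3], t[3]),
          c(b[1], b[2], t[3], t[2]),
          c(b[1], t[1], t[2], t[3]))
  } else {
    rbind(c(b[1], b[2], b[3], t[2]),
          c(b[1], t[2], b[3], t[3]),
          c(b[1], t[1], t[2], t[3]))
  }
}

.tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  d <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
     a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
     a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

#' Generate a synthetic tetrahedral disc mesh
#'
#' Meshes the parametric disc of a [segment_spec()] with linear tetrahedra:
#' a structured square grid is mapped onto the superellipse cross-section
#' (elliptical square-to-disc mapping, so there is no central singularity),
#' extruded through the wedged/skewed height profile, and each cell is split
#' into six conforming tetrahedra. Elements are labeled `"NP"` when their
#' centroid falls inside the inner nucleus superellipse and `"AF"` otherwise;
#' fiber frames are then attached with [assign_fiber_frames()] and
#' characteristic lengths with [characteristic_length()].
#'
#' The construction is fully deterministic; `seed` is recorded and reserved
#' for optional node jitter (`jitter > 0`).
#'
#' @param spec An [segment_spec()].
#' @param seed Integer seed (stored; used only when `jitter > 0`).
#' @param jitter Relative in-plane node jitter (fraction of element size),
#'   default 0.
#' @param phi Fiber angle passed to [assign_fiber_frames()].
#' @return An `ivd_mesh`: list with `nodes` (N x 3, mm), `tets` (E x 4 node
#'   indices), `region` (`"AF"`/`"NP"` per element), `M1`, `M2` (E x 3 unit
#'   fiber directions, `NA` for NP), `l_c` (mm), `volume` (mm^3 per element),
#'   `cranial_nodes`, `caudal_nodes`, `basis`, and the `spec`.
#' @examples
#' mesh <- generate_segment(segment_spec(element_size = 6))
#' table(mesh$region)
#' @export
generate_segment <- function(spec, seed = 1L, jitter = 0, phi = 30) {
  stopifnot(inherits(spec, "ivd_segment_spec"))
  a <- spec$r_lat; b <- spec$r_ap; m <- spec$exponent
  h0 <- (spec$h_ant + spec$h_post) / 2
  hmin <- min(spec$h_ant, spec$h_post)
  # thin degenerated discs are legitimate targets (flat elements are the
  # tetrahedral selling point); only refuse hopeless size/height ratios
  if (spec$element_size > 2.5 * hmin)
    stop(sprintf(
      "element size %g mm exceeds 2.5x the minimum disc height %g mm; reduce element_size",
      spec$element_size, hmin))
  nu <- max(4L, as.integer(ceiling(2 * a / spec$element_size)))
  nz <- max(2L, as.integer(round(h0 / spec$element_size)))

  u <- seq(-1, 1, length.out = nu + 1L)
  g <- expand.grid(u = u, v = u)
  # concentric (Shirley-Chiu) square-to-disc mapping, then radial scale to
  # the superellipse; preserves cell quality far better near the wall than
  # the naive elliptical stretch
  p <- .square_to_disc(g$u, g$v)
  px <- p[, 1]
  py <- p[, 2]
  th <- atan2(py, px)
  R <- .se_radius(th, a, b, m)
  x0 <- px * R
  y0 <- py * R
  # Laplacian smoothing of interior footprint nodes: blunts the diagonal
  # creases of the concentric mapping that otherwise produce sliver tets
  interior <- matrix(TRUE, nu + 1L, nu + 1L)
  interior[c(1L, nu + 1L), ] <- FALSE
  interior[, c(1L, nu + 1L)] <- FALSE
  xg <- matrix(x0, nu + 1L); yg <- matrix(y0, nu + 1L)
  for (it in 1:12) {
    xa <- (xg[1:(nu - 1L), 2:nu] + xg[3:(nu + 1L), 2:nu] +
             xg[2:nu, 1:(nu - 1L)] + xg[2:nu, 3:(nu + 1L)]) / 4
    ya <- (yg[1:(nu - 1L), 2:nu] + yg[3:(nu + 1L), 2:nu] +
             yg[2:nu, 1:(nu - 1L)] + yg[2:nu, 3:(nu + 1L)]) / 4
    xg[2:nu, 2:nu] <- 0.4 * xg[2:nu, 2:nu] + 0.6 * xa
    yg[2:nu, 2:nu] <- 0.4 * yg[2:nu, 2:nu] + 0.6 * ya
  }
  x0 <- as.numeric(xg)
  y0 <- as.numeric(yg)
  if (jitter > 0) {
    set.seed(seed)
    r2 <- px^2 + py^2
    amp <- jitter * spec$element_size * pmax(0, 1 - r2) # keep the wall exact
    x0 <- x0 + stats::rnorm(length(x0), sd = amp)
    y0 <- y0 + stats::rnorm(length(y0), sd = amp)
  }

  npl <- (nu + 1L)^2
  zeta <- seq(0, 1, length.out = nz + 1L)
  hy <- h0 + (spec$h_ant - spec$h_post) / 2 * (y0 / b)
  nodes <- matrix(0, npl * (nz + 1L), 3)
  for (l in seq_len(nz + 1L)) {
    zl <- zeta[l]
    s <- 1 + 4 * spec$bulge * zl * (1 - zl)
    rows <- ((l - 1L) * npl + 1L):(l * npl)
    nodes[rows, 1] <- s * x0
    nodes[rows, 2] <- s * y0 + zl * spec$skew
    nodes[rows, 3] <- zl * hy
  }

  # triangulate the footprint (shorter diagonal per grid quad), then extrude
  # each triangle into nz prisms and split each prism into 3 conforming tets
  fid <- function(i, j) (j - 1L) * (nu + 1L) + i
  tris <- matrix(0L, 2L * nu * nu, 3L)
  trow <- 0L
  for (j in seq_len(nu)) for (i in seq_len(nu)) {
    n00 <- fid(i, j); n10 <- fid(i + 1L, j)
    n01 <- fid(i, j + 1L); n11 <- fid(i + 1L, j + 1L)
    d1 <- (x0[n00] - x0[n11])^2 + (y0[n00] - y0[n11])^2
    d2 <- (x0[n10] - x0[n01])^2 + (y0[n10] - y0[n01])^2
    if (d1 <= d2) {
      tris[trow + 1L, ] <- c(n00, n10, n11)
      tris[trow + 2L, ] <- c(n00, n11, n01)
    } else {
      tris[trow + 1L, ] <- c(n00, n10, n01)
      tris[trow + 2L, ] <- c(n10, n11, n01)
    }
    trow <- trow + 2L
  }
  # counterclockwise footprint triangles so extruded prisms are upright
  sa <- (x0[tris[, 2]] - x0[tris[, 1]]) * (y0[tris[, 3]] - y0[tris[, 1]]) -
    (x0[tris[, 3]] - x0[tris[, 1]]) * (y0[tris[, 2]] - y0[tris[, 1]])
  cw <- sa < 0
  tris[cw, 2:3] <- tris[cw, 3:2]
  tets <- matrix(0L, nrow(tris) * nz * 3L, 4L)
  row <- 0L
  for (l in seq_len(nz)) {
    off_b <- (l - 1L) * npl
    for (tr in seq_len(nrow(tris))) {
      bt <- tris[tr, ] + off_b
      tets[row + 1:3, ] <- .prism_tets(bt, bt + npl)
      row <- row + 3L
    }
  }

  storage.mode(tets) <- "integer"
  vol <- .tet_volumes(nodes, tets)
  neg <- vol < 0
  if (any(neg)) { # orientation fix keeps face sharing intact
    tmp <- tets[neg, 3L]
    tets[neg, 3L] <- tets[neg, 4L]
    tets[neg, 4L] <- tmp
    vol[neg] <- -vol[neg]
  }
  if (any(vol <= 0))
    stop("meshing failure: degenerate tetrahedra; the in-plane grid of ",
         nu, " cells cannot resolve the cross-section, reduce element_size")

  cen <- (nodes[tets[, 1], ] + nodes[tets[, 2], ] +
            nodes[tets[, 3], ] + nodes[tets[, 4], ]) / 4
  # classify on the caudal-plane footprint (undo skew/bulge tilt via z-fraction)
  zfrac <- pmin(pmax(cen[, 3] / (h0 + (spec$h_ant - spec$h_post) / 2 *
                                   (cen[, 2] / b)), 0), 1)
  sfac <- 1 + 4 * spec$bulge * zfrac * (1 - zfrac)
  cx <- cen[, 1] / sfac
  cy <- (cen[, 2] - zfrac * spec$skew) / sfac
  sc <- sqrt(spec$nucleus_fraction)
  inside <- (abs(cx / (a * sc))^m +
               abs((cy - spec$nucleus_offset) / (b * sc))^m) <= 1
  region <- ifelse(inside, "NP", "AF")
  if (!any(region == "AF") || !any(region == "NP"))
    stop("meshing failure: empty AF or NP region; adjust nucleus_fraction or element_size")

  mesh <- structure(
    list(nodes = nodes, tets = tets, region = region,
         M1 = matrix(NA_real_, nrow(tets), 3),
         M2 = matrix(NA_real_, nrow(tets), 3),
         l_c = rep(NA_real_, nrow(tets)), volume = vol,
         cranial_nodes = as.integer(nz * npl + seq_len(npl)),
         caudal_nodes = seq_len(npl),
         basis = diag(3), spec = spec, seed = as.integer(seed)),
    class = "ivd_mesh"
  )
  mesh <- assign_fiber_frames(mesh, phi = phi)
  mesh$l_c <- characteristic_length(mesh)
  mesh
}

#' @export
print.ivd_mesh <- function(x, ...) {
  cat(sprintf(
    "<ivd_mesh> %d nodes, %d tets (%d AF / %d NP), volume %.1f mm^3\n",
    nrow(x$nodes), nrow(x$tets), sum(x$region == "AF"),
    sum(x$region == "NP"), sum(x$volume)))
  invisible(x)
}

#' Assign collagen fiber frames to annulus elements
#'
#' For every AF element, builds the local orthonormal basis at the element
#' centroid — \eqn{\hat e_1} tangent to the disc circumference (the
#' superellipse level curve through the centroid), \eqn{\hat e_2} the local
#' endplate-to-endplate direction orthonormalized against \eqn{\hat e_1},
#' \eqn{\hat e_3 = \hat e_1 \times \hat e_2} outward radial — and stores the
#' two fiber directions \eqn{M_{1,2} = \cos\Phi\,\hat e_1 \pm
#' \sin\Phi\,\hat e_2}.
#'
#' @param mesh An `ivd_mesh`.
#' @param phi Fiber angle in degrees about the local transverse plane.
#' @return The mesh with `M1`, `M2` populated for AF elements and the Euler
#'   frame stored as attribute `"fiber_phi"`.
#' @export
assign_fiber_frames <- function(mesh, phi = 30) {
  stopifnot(inherits(mesh, "ivd_mesh"))
  spec <- mesh$spec
  af <- which(mesh$region == "AF")
  cen <- (mesh$nodes[mesh$tets[af, 1], ] + mesh$nodes[mesh$tets[af, 2], ] +
            mesh$nodes[mesh$tets[af, 3], ] + mesh$nodes[mesh$tets[af, 4], ]) / 4
  a <- spec$r_lat; b <- spec$r_ap; m <- spec$exponent
  h0 <- (spec$h_ant + spec$h_post) / 2
  zfrac <- pmin(pmax(cen[, 3] / (h0 + (spec$h_ant - spec$h_post) / 2 *
                                   (cen[, 2] / b)), 0), 1)
  sfac <- 1 + 4 * spec$bulge * zfrac * (1 - zfrac)
  cx <- cen[, 1] / sfac
  cy <- (cen[, 2] - zfrac * spec$skew) / sfac
  r <- sqrt(cx^2 + cy^2)
  if (any(r < 1e-9))
    stop("fiber frame undefined: AF element centroid on the disc axis")
  # outward normal of the superellipse level curve |x/a|^m + |y/b|^m = const
  gx <- m * abs(cx / a)^(m - 1) * sign(cx) / a
  gy <- m * abs(cy / b)^(m - 1) * sign(cy) / b
  gn <- sqrt(gx^2 + gy^2)
  # counterclockwise circumferential tangent
  e1 <- cbind(-gy / gn, gx / gn, 0)
  # local endplate-to-endplate direction (skew shear + wedge slope)
  dh <- (spec$h_ant - spec$h_post) / 2 / b
  d <- cbind(0 * cx, rep(spec$skew, length(cx)),
             h0 + dh * cy - 0) # top minus bottom at fixed footprint
  d[, 3] <- pmax(d[, 3], 1e-6)
  d <- d / sqrt(rowSums(d^2))
  proj <- rowSums(d * e1)
  e2 <- d - proj * e1
  e2 <- e2 / sqrt(rowSums(e2^2))
  cs <- cos(phi * pi / 180); sn <- sin(phi * pi / 180)
  mesh$M1[af, ] <- cs * e1 + sn * e2
  mesh$M2[af, ] <- cs * e1 - sn * e2
  attr(mesh, "fiber_phi") <- phi
  if (phi == 0) attr(mesh, "fiber_degenerate") <- TRUE
  mesh
}

#' Characteristic element lengths
#'
#' The minimum-altitude length \eqn{l_c = 3 V_e / A_{max}} of each
#' tetrahedron (volume over largest face area), the conservative choice for
#' the critical-time-step estimate.
#'
#' @param mesh An `ivd_mesh`.
#' @return Numeric vector of lengths (mm) per element.
#' @export
characteristic_length <- function(mesh) {
  nodes <- mesh$nodes; tets <- mesh$tets
  V <- .tet_volumes(nodes, tets)
  if (any(V <= 0))
    stop("degenerate element(s): ", paste(utils::head(which(V <= 0)), collapse = ", "))
  tri_area <- function(p, q, r) {
    u <- q - p; w <- r - p
    cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
    cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
    cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
    sqrt(cx^2 + cy^2 + cz^2) / 2
  }
  p1 <- nodes[tets[, 1], , drop = FALSE]; p2 <- nodes[tets[, 2], , drop = FALSE]
  p3 <- nodes[tets[, 3], , drop = FALSE]; p4 <- nodes[tets[, 4], , drop = FALSE]
  Amax <- pmax(tri_area(p2, p3, p4), tri_area(p1, p3, p4),
               tri_area(p1, p2, p4), tri_area(p1, p2, p3))
  3 * V / Amax
}
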