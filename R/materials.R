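#' Nucleus pulposus material (compressible Mooney-Rivlin)
#'
#' The nucleus pulposus (NP) is modeled as an isotropic compressible
#' Mooney-Rivlin solid with a decoupled distortional/dilatational strain
#' energy,
#' \deqn{\Psi_{NP} = b_{10}(\bar I_1 - 3) + b_{01}(\bar I_2 - 3) +
#'   \tfrac{k_{NP}}{2}(J - 1)^2,}
#' where \eqn{\bar I_1, \bar I_2} are the distortional invariants and
#' \eqn{J = \det F}.
#'
#' Parameters are given in kPa by default (the unit in which disc moduli are
#' conventionally reported) and stored internally in Pa; all package functions
#' return stresses and energy densities in Pa.
#'
#' @param b10,b01 Stress-like Mooney-Rivlin constants (kPa unless
#'   `units = "Pa"`). `b10` must be positive, `b01` non-negative.
#' @param k Bulk modulus (same units).
#' @param rho0 Reference density in kg/m^3 (default 1000, soft tissue is
#'   essentially water).
#' @param units `"kPa"` (default) or `"Pa"` for the stress-like inputs.
#' @return An object of class `c("ivd_np_material", "ivd_material")`: a list
#'   with fields `b10`, `b01`, `k` (Pa) and `rho0` (kg/m^3).
#' @seealso [af_material()], [material_preset()], [bulk_from_poisson()]
#' @examples
#' np <- np_material(b10 = 0.12, b01 = 0.03, k = 29.9)
#' np$k   # Pa
#' @export
np_material <- function(b10, b01, k, rho0 = 1000, units = c("kPa", "Pa")) {
  units <- match.arg(units)
  s <- if (units == "kPa") 1e3 else 1
  stopifnot(is.numeric(b10), is.numeric(b01), is.numeric(k), is.numeric(rho0))
  if (b10 <= 0) stop("b10 must be > 0")
  if (b01 < 0) stop("b01 must be >= 0")
  if (k <= 0) stop("bulk modulus k must be > 0")
  if (rho0 <= 0) stop("rho0 must be > 0")
  structure(
    list(b10 = b10 * s, b01 = b01 * s, k = k * s, rho0 = rho0),
    class = c("ivd_np_material", "ivd_material")
  )
}

#' Annulus fibrosus material (fiber-reinforced Mooney-Rivlin)
#'
#' The annulus fibrosus (AF) is modeled as a Mooney-Rivlin matrix reinforced
#' by two collagen fiber families with reference directions
#' \eqn{M_1, M_2} at \eqn{\pm\phi} about the local transverse plane:
#' \deqn{\Psi_{AF} = c_{10}(\bar I_1 - 3) + c_{01}(\bar I_2 - 3) +
#'   \tfrac{k_{AF}}{2}(J-1)^2 + \sum_{i=1}^{2} \frac{a_1}{a_2}
#'   \left[\exp\!\big(a_2 \langle \bar I_{M_i} - 1\rangle^2\big) - 1\right],}
#' with fiber invariants \eqn{\bar I_{M_i} = M_i \cdot \bar C M_i} (squared
#' distortional fiber stretch) and Macaulay bracket
#' \eqn{\langle x \rangle = (|x|+x)/2}: crimped collagen fibers carry load
#' only in tension.
#'
#' @param c10,c01 Matrix Mooney-Rivlin constants (kPa unless `units = "Pa"`).
#' @param a1 Fiber stress-like constant (same units), non-negative.
#' @param a2 Dimensionless fiber exponent, positive.
#' @param k Bulk modulus (same units).
#' @param rho0 Reference density, kg/m^3.
#' @param phi Fiber angle in degrees about the local transverse plane,
#'   strictly between 0 and 90. Default 30 (average lamellar orientation).
#' @param units `"kPa"` (default) or `"Pa"`.
#' @return An object of class `c("ivd_af_material", "ivd_material")` with
#'   stress-like fields in Pa, plus `a2`, `rho0` and `phi`.
#' @examples
#' af <- af_material(c10 = 0.18, c01 = 0.045, a1 = 2, a2 = 100, k = 4.35)
#' @export
af_material <- function(c10, c01, a1, a2, k, rho0 = 1000, phi = 30,
                        units = c("kPa", "Pa")) {
  units <- match.arg(units)
  s <- if (units == "kPa") 1e3 else 1
  if (c10 <= 0) stop("c10 must be > 0")
  if (c01 < 0) stop("c01 must be >= 0")
  if (a1 < 0) stop("a1 must be >= 0")
  if (a2 <= 0) stop("a2 must be > 0")
  if (k <= 0) stop("bulk modulus k must be > 0")
  if (rho0 <= 0) stop("rho0 must be > 0")
  if (phi <= 0 || phi >= 90) stop("fiber angle phi must lie in (0, 90) degrees")
  structure(
    list(c10 = c10 * s, c01 = c01 * s, a1 = a1 * s, a2 = a2, k = k * s,
         rho0 = rho0, phi = phi),
    class = c("ivd_af_material", "ivd_material")
  )
}

#' @export
print.ivd_material <- function(x, ...) {
  kind <- if (inherits(x, "ivd_af_material")) "annulus fibrosus" else "nucleus pulposus"
  cat("<ivd_material:", kind, ">\n")
  for (nm in names(x)) {
    unit <- if (nm %in% c("b10", "b01", "c10", "c01", "a1", "k")) " Pa"
            else if (nm == "rho0") " kg/m^3"
            else if (nm == "phi") " deg" else ""
    cat(sprintf("  %-5s %g%s\n", nm, x[[nm]], unit))
  }
  invisible(x)
}

# normalized parameter list used by the internal batch evaluator:
# p10/p01/k always present; a1 = 0 marks "no fibers".
mat_pars <- function(mat) {
  if (inherits(mat, "ivd_af_material")) {
    list(p10 = mat$c10, p01 = mat$c01, k = mat$k, a1 = mat$a1, a2 = mat$a2,
         rho0 = mat$rho0)
  } else if (inherits(mat, "ivd_np_material")) {
    list(p10 = mat$b10, p01 = mat$b01, k = mat$k, a1 = 0, a2 = 1,
         rho0 = mat$rho0)
  } else stop("not an ivd_material")
}

#' Bulk modulus from Poisson's ratio
#'
#' Reconstructs the bulk modulus implied by a pair of Mooney-Rivlin constants
#' and a target Poisson's ratio, using the small-strain isotropic identity
#' \eqn{k = 2\mu_0 (1+\nu) / (3 (1 - 2\nu))} with ground-state shear modulus
#' \eqn{\mu_0 = 2(c_{10} + c_{01})}. With the disc presets this reproduces the
#' shipped bulk moduli: (0.12, 0.03, 0.495) gives 29.9 kPa for the nucleus and
#' (0.18, 0.045, 0.45) gives 4.35 kPa for the annulus matrix.
#'
#' @param c10,c01 Mooney-Rivlin constants (any stress unit; the result is in
#'   the same unit).
#' @param nu Poisson's ratio, `0 <= nu < 0.5`.
#' @return Bulk modulus in the unit of `c10`.
#' @examples
#' bulk_from_poisson(0.12, 0.03, 0.495)  # 29.9 (kPa in, kPa out)
#' @export
bulk_from_poisson <- function(c10, c01, nu) {
  if (any(nu >= 0.5)) stop("nu must be < 0.5 (incompressible limit)")
  if (any(nu < 0)) stop("nu must be >= 0")
  mu0 <- 2 * (c10 + c01)
  2 * mu0 * (1 + nu) / (3 * (1 - 2 * nu))
}

#' Read a flat TOML material file
#'
#' Reads the minimal flat `key = value` TOML subset used by the shipped
#' material presets (one optional `[table]` header, numeric or quoted string
#' values, `#` comments). Not a general TOML parser.
#'
#' @param path File path.
#' @return Named list of values.
#' @keywords internal
read_flat_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3) stop("malformed TOML line: ", ln)
    key <- m[2]; val <- trimws(m[3])
    if (grepl('^".*"$', val)) {
      out[[key]] <- gsub('^"|"$', "", val)
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stop("unsupported TOML value for ", key, ": ", val)
      out[[key]] <- num
    }
  }
  out
}

#' Shipped material parameter presets
#'
#' Loads one of the material presets installed with the package:
#' \describe{
#'   \item{`"np_table1"`}{Nucleus pulposus, literature values
#'     (b10 = 0.12, b01 = 0.03, k = 29.9 kPa).}
#'   \item{`"af_table1"`}{Annulus fibrosus, literature values
#'     (c10 = 0.18, c01 = 0.045, a1 = 2, a2 = 100, k = 4.35 kPa).}
#'   \item{`"af_table3"`}{Annulus fibrosus calibrated against mean cadaveric
#'     range-of-motion curves (c10 = 0.016, c01 = 0.001, a1 = 1, a2 = 151,
#'     k = 170 kPa).}
#' }
#'
#' @param name Preset name.
#' @param rho0 Reference density override (kg/m^3).
#' @return An [np_material()] or [af_material()] object.
#' @examples
#' material_preset("af_table1")
#' @export
material_preset <- function(name = c("np_table1", "af_table1", "af_table3"),
                            rho0 = 1000) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".toml"), package = "ivdfem")
  if (!nzchar(path)) stop("preset file not found for ", name)
  material_from_toml(path, rho0 = rho0)
}

#' Load a material from a TOML parameter file
#'
#' The file is a flat TOML table with a `tissue` key (`"np"` or `"af"`) and
#' the stress-like parameters in kPa (key `units = "kPa"`, the only supported
#' value).
#'
#' @param path TOML file path.
#' @param rho0 Reference density (kg/m^3), not stored in the preset files.
#' @return An `ivd_material`.
#' @export
material_from_toml <- function(path, rho0 = 1000) {
  v <- read_flat_toml(path)
  units <- if (!is.null(v$units)) v$units else "kPa"
  if (!identical(units, "kPa")) stop("preset units must be kPa")
  if (identical(v$tissue, "np")) {
    np_material(v$b10, v$b01, v$k, rho0 = rho0, units = "kPa")
  } else if (identical(v$tissue, "af")) {
    phi <- if (!is.null(v$phi)) v$phi else 30
    af_material(v$c10, v$c01, v$a1, v$a2, v$k, rho0 = rho0, phi = phi,
                units = "kPa")
  } else stop("TOML file must set tissue = \"np\" or \"af\"")
}
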