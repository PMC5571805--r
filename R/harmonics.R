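## Real spherical harmonics up to l = 4, orthonormal convention
## (integral of Y^2 over the sphere = 1). Multipole populations P_lm in this
## package are coefficients on this basis; the Fourier transform pair
## rho_lm(r) = R_l(r) Y_lm(rhat)  <->  4 pi i^l <j_l>(s) Y_lm(hhat)
## holds with the same Y on both sides, so real- and reciprocal-space code
## share one table.

#' Names of the multipole basis functions
#'
#' @param l_max highest order (0 to 4).
#' @param include_monopole include the l = 0 entry (`"P00"`, the valence
#'   monopole) in the list.
#' @return character vector such as `"P10"`, `"P11+"`, `"P11-"`, ...
#' @export
multipole_names <- function(l_max = 4, include_monopole = FALSE) {
  out <- character(0)
  for (l in seq(0, l_max)) {
    if (l == 0) { if (include_monopole) out <- c(out, "P00"); next }
    nm <- paste0("P", l, "0")
    for (m in seq_len(l)) nm <- c(nm, paste0("P", l, m, "+"), paste0("P", l, m, "-"))
    out <- c(out, nm)
  }
  out
}

## parse "P32-" -> c(l = 3, m = 2, s = -1)
parse_multipole_name <- function(nm) {
  l <- as.integer(substr(nm, 2, 2))
  m <- as.integer(substr(nm, 3, 3))
  s <- if (nchar(nm) >= 4 && substr(nm, 4, 4) == "-") -1L else 1L
  c(l = l, m = m, s = s)
}

#' Evaluate real spherical harmonics on unit vectors
#'
#' @param u n x 3 matrix of unit vectors.
#' @param names character vector of basis-function names (see
#'   [multipole_names()]); `"P00"` gives the constant 1/sqrt(4 pi).
#' @return n x length(names) matrix of values.
#' @export
real_spherical_harmonics <- function(u, names = multipole_names(4)) {
  if (!is.matrix(u)) u <- matrix(u, ncol = 3)
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  out <- matrix(0, nrow(u), length(names))
  colnames(out) <- names
  for (j in seq_along(names)) {
    out[, j] <- switch(names[j],
      "P00"  = rep(0.5 / sqrt(pi), length(x)),
      "P10"  = sqrt(3 / (4 * pi)) * z,
      "P11+" = sqrt(3 / (4 * pi)) * x,
      "P11-" = sqrt(3 / (4 * pi)) * y,
      "P20"  = 0.25 * sqrt(5 / pi) * (3 * z^2 - 1),
      "P21+" = 0.5 * sqrt(15 / pi) * x * z,
      "P21-" = 0.5 * sqrt(15 / pi) * y * z,
      "P22+" = 0.25 * sqrt(15 / pi) * (x^2 - y^2),
      "P22-" = 0.5 * sqrt(15 / pi) * x * y,
      "P30"  = 0.25 * sqrt(7 / pi) * (5 * z^3 - 3 * z),
      "P31+" = 0.25 * sqrt(21 / (2 * pi)) * x * (5 * z^2 - 1),
      "P31-" = 0.25 * sqrt(21 / (2 * pi)) * y * (5 * z^2 - 1),
      "P32+" = 0.25 * sqrt(105 / pi) * z * (x^2 - y^2),
      "P32-" = 0.5 * sqrt(105 / pi) * x * y * z,
      "P33+" = 0.25 * sqrt(35 / (2 * pi)) * x * (x^2 - 3 * y^2),
      "P33-" = 0.25 * sqrt(35 / (2 * pi)) * y * (3 * x^2 - y^2),
      "P40"  = (3 / 16) * sqrt(1 / pi) * (35 * z^4 - 30 * z^2 + 3),
      "P41+" = (3 / 4) * sqrt(5 / (2 * pi)) * x * z * (7 * z^2 - 3),
      "P41-" = (3 / 4) * sqrt(5 / (2 * pi)) * y * z * (7 * z^2 - 3),
      "P42+" = (3 / 8) * sqrt(5 / pi) * (x^2 - y^2) * (7 * z^2 - 1),
      "P42-" = (3 / 4) * sqrt(5 / pi) * x * y * (7 * z^2 - 1),
      "P43+" = (3 / 4) * sqrt(35 / (2 * pi)) * z * x * (x^2 - 3 * y^2),
      "P43-" = (3 / 4) * sqrt(35 / (2 * pi)) * z * y * (3 * x^2 - y^2),
      "P44+" = (3 / 16) * sqrt(35 / pi) * (x^4 - 6 * x^2 * y^2 + y^4),
      "P44-" = (3 / 4) * sqrt(35 / pi) * x * y * (x^2 - y^2),
      stop("unknown harmonic name '", names[j], "'")
    )
  }
  out
}

rot_z <- function(phi) {
  c1 <- cos(phi); s1 <- sin(phi)
  matrix(c(c1, -s1, 0, s1, c1, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

#' Point-group operations of a local-symmetry code
#'
#' Returns Cartesian 3x3 matrices (in the atom's local frame: z is the
#' primary axis, the mirror `m` is the local xz plane) generating the local
#' point group used to restrict multipoles. The cylindrical codes are
#' represented by a set of generic rotations about z, which is sufficient
#' for the numerical invariance test on polynomials of degree <= 4.
#'
#' @param code one of `"none"`, `"m"`, `"mm2"`, `"3"`, `"cyl"`, `"cyl_mm"`.
#' @return list of 3x3 matrices.
#' @export
local_symmetry_ops <- function(code) {
  mir_y <- diag(c(1, -1, 1))   # mirror = local xz plane
  mir_x <- diag(c(-1, 1, 1))   # mirror = local yz plane
  mir_z <- diag(c(1, 1, -1))   # mirror perpendicular to z
  generic <- c(0.831966326131, 2.261947710589, 4.009231268123,
               5.103508963902, 1.459284801433)
  switch(code,
    "none"   = list(diag(3)),
    "m"      = list(mir_y),
    "mm2"    = list(mir_x, mir_y),
    "3"      = list(rot_z(2 * pi / 3)),
    "cyl"    = lapply(generic, rot_z),
    "cyl_mm" = c(lapply(generic, rot_z), list(mir_y, mir_z)),
    stop("unknown local-symmetry code '", code, "'; valid codes: ",
         "none, m, mm2, 3, cyl, cyl_mm")
  )
}

#' Multipoles allowed by a local point group
#'
#' Determines, by direct numerical invariance of each real spherical
#' harmonic under every generator of the local point group, which multipole
#' populations are allowed to be nonzero. Symmetry tables are never
#' hard-coded: a function is allowed iff max_u |d(Ru) - d(u)| < 1e-8 over a
#' fixed set of probe directions for every generator R.
#'
#' @param local_symmetry code accepted by [local_symmetry_ops()].
#' @param l_max highest multipole order, 0 to 4.
#' @return named logical vector over the basis functions up to `l_max`
#'   (including `"P00"`, always allowed).
#' @export
allowed_multipoles <- function(local_symmetry, l_max = 4) {
  if (!is.numeric(l_max) || l_max < 0 || l_max > 4)
    stop("l_max must lie in [0, 4]")
  ops <- local_symmetry_ops(local_symmetry)
  nms <- multipole_names(l_max, include_monopole = TRUE)
  u <- probe_directions()
  Y <- real_spherical_harmonics(u, nms)
  ok <- rep(TRUE, length(nms)); names(ok) <- nms
  for (R in ops) {
    Yr <- real_spherical_harmonics(u %*% t(R), nms)
    dev <- apply(abs(Yr - Y), 2, max)
    ok <- ok & (dev < 1e-8)
  }
  ok
}

probe_directions <- function(n = 62) {
  ## deterministic quasi-uniform directions (Fibonacci sphere)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}
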