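#' Unit cell
#'
#' Construct a unit cell from lengths (angstrom) and angles (degrees).
#' The object caches the direct metric tensor `G`, the reciprocal metric
#' `Gstar`, the orthogonalization matrix `M` (fractional -> Cartesian,
#' standard PDB convention: a along x, b in the xy plane) and the cell
#' volume.
#'
#' @param a,b,c cell edge lengths in angstrom, > 0.
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell`.
#' @examples
#' uc <- unit_cell(10, 10, 10)
#' stol(uc, c(1, 0, 0))  # 0.05
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(a > 0, b > 0, c > 0)
  ang <- c(alpha, beta, gamma)
  if (any(ang <= 0) || any(ang >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  G <- matrix(c(a * a,     a * b * cg, a * c * cb,
                a * b * cg, b * b,     b * c * ca,
                a * c * cb, b * c * ca, c * c), 3, 3)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("cell metric tensor is not positive definite")
  Gstar <- solve(G)
  V <- sqrt(det(G))
  sg <- sin(gamma * pi / 180)
  # orthogonalization: a along x, b in xy plane
  M <- matrix(c(a, b * cg, c * cb,
                0, b * sg, c * (ca - cb * cg) / sg,
                0, 0,      V / (a * b * sg)), 3, 3, byrow = TRUE)
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 G = G, Gstar = Gstar, M = M,
                 # reciprocal orthogonalization: hkl -> Cartesian (A^-1)
                 Bstar = t(solve(M)),
                 volume = V),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell  a=%.4f b=%.4f c=%.4f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.2f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Resolution coordinate sin(theta)/lambda
#'
#' Computes stol = 1/(2 d_hkl) from the reciprocal metric. The origin
#' reflection (0,0,0) maps to 0 (flagged unusable downstream).
#'
#' @param cell a [unit_cell()].
#' @param hkl integer vector of length 3, or an n x 3 matrix of indices.
#' @return numeric vector of sin(theta)/lambda values in 1/angstrom.
#' @export
stol <- function(cell, hkl) {
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  0.5 * sqrt(rowSums((h %*% cell$Gstar) * h))
}

## Cartesian reciprocal vectors (rows), length = 1/d = 2*stol
hkl_cart <- function(cell, hkl) {
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  h %*% t(cell$Bstar)
}

frac_to_cart <- function(cell, x) {
  m <- if (is.matrix(x)) x else matrix(x, ncol = 3)
  m %*% t(cell$M)
}

cart_to_frac <- function(cell, x) {
  m <- if (is.matrix(x)) x else matrix(x, ncol = 3)
  m %*% t(solve(cell$M))
}
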