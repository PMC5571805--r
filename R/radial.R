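## Single-zeta Slater radial model of the atomic density.
##
## Each shell contributes a normalized density-type radial function
##   R(r) = N r^n exp(-zeta r),  N = zeta^(n+3) / (n+2)!,
## so that integral R(r) r^2 dr = 1, and the shell's form-factor
## contribution is n_el * <j_0>(s). The core is the sum of the inner
## shells; the valence shell carries the kappa-refinable monopole and the
## kappa'-refinable deformation functions. Exponents (Bohr^-1) follow
## single-zeta best-atom values after Clementi & Raimondi; they are a
## bundled, swappable basis, not a fit to any external databank.

BOHR <- 0.529177210903  # angstrom

slater_table <- function() {
  ## per element: core shells (n = 2(nshell-1), zeta_orb Bohr^-1, electrons)
  ## and one valence shell; n_l = radial powers for deformation l = 1..4
  list(
    H  = list(Z = 1, core = NULL,
              valence = list(n = 0, zeta = 1.000, nel = 1),
              def_n = c(1, 2, 3, 4), def_zeta = 1.000),
    B  = list(Z = 5, core = list(list(n = 0, zeta = 4.680, nel = 2)),
              valence = list(n = 2, zeta = 1.288, nel = 3),
              def_n = c(2, 2, 3, 4), def_zeta = 1.288),
    C  = list(Z = 6, core = list(list(n = 0, zeta = 5.673, nel = 2)),
              valence = list(n = 2, zeta = 1.608, nel = 4),
              def_n = c(2, 2, 3, 4), def_zeta = 1.608),
    N  = list(Z = 7, core = list(list(n = 0, zeta = 6.665, nel = 2)),
              valence = list(n = 2, zeta = 1.924, nel = 5),
              def_n = c(2, 2, 3, 4), def_zeta = 1.924),
    O  = list(Z = 8, core = list(list(n = 0, zeta = 7.658, nel = 2)),
              valence = list(n = 2, zeta = 2.246, nel = 6),
              def_n = c(2, 2, 3, 4), def_zeta = 2.246),
    F  = list(Z = 9, core = list(list(n = 0, zeta = 8.650, nel = 2)),
              valence = list(n = 2, zeta = 2.564, nel = 7),
              def_n = c(2, 2, 3, 4), def_zeta = 2.564),
    Si = list(Z = 14, core = list(list(n = 0, zeta = 13.575, nel = 2),
                                  list(n = 2, zeta = 4.903, nel = 8)),
              valence = list(n = 4, zeta = 1.530, nel = 4),
              def_n = c(4, 4, 4, 4), def_zeta = 1.530),
    P  = list(Z = 15, core = list(list(n = 0, zeta = 14.558, nel = 2),
                                  list(n = 2, zeta = 5.350, nel = 8)),
              valence = list(n = 4, zeta = 1.740, nel = 5),
              def_n = c(4, 4, 4, 4), def_zeta = 1.740),
    S  = list(Z = 16, core = list(list(n = 0, zeta = 15.541, nel = 2),
                                  list(n = 2, zeta = 5.810, nel = 8)),
              valence = list(n = 4, zeta = 1.930, nel = 6),
              def_n = c(4, 4, 4, 4), def_zeta = 1.930),
    Cl = list(Z = 17, core = list(list(n = 0, zeta = 16.524, nel = 2),
                                  list(n = 2, zeta = 6.260, nel = 8)),
              valence = list(n = 4, zeta = 2.100, nel = 7),
              def_n = c(4, 4, 4, 4), def_zeta = 2.100)
  )
}

element_entry <- function(element) {
  tab <- slater_table()
  e <- tab[[element]]
  if (is.null(e))
    stop("element '", element, "' is not in the bundled Slater table (",
         paste(names(tab), collapse = ", "), ")")
  e
}

## zeta for density functions in angstrom^-1 (orbital zeta doubled for the
## density of a squared orbital)
density_zeta <- function(zeta_orb) 2 * zeta_orb / BOHR

#' Fourier-Bessel transform of a normalized Slater function
#'
#' Computes `<j_l>(s) = integral R(r) j_l(4 pi s r) r^2 dr` for
#' `R(r) = N r^n exp(-zeta r)` with `N = zeta^(n+3)/(n+2)!`, in closed form
#' (rational expressions from `int r^q exp(-zeta r) exp(iKr) dr =
#' q!/(zeta - iK)^(q+1)`), with a Taylor-series fallback at small `K r` to
#' avoid cancellation. `<j_0>(0) = 1`, `<j_l>(0) = 0` for l >= 1.
#'
#' @param l spherical-Bessel order, 0 to 4.
#' @param zeta density exponent in 1/angstrom (> 0).
#' @param n radial power (n >= l required for l >= 1... n >= 0).
#' @param s sin(theta)/lambda values (1/angstrom), vectorized.
#' @return numeric vector of transform values.
#' @export
fourier_bessel <- function(l, zeta, n, s) {
  stopifnot(l %in% 0:4, zeta > 0, n >= 0)
  if (l >= 1 && n < l - 1)
    stop("radial power n too small for l = ", l)
  K <- 4 * pi * s
  out <- numeric(length(K))
  ## switch point: series is accurate and stable when K <~ zeta
  small <- K * (n + 3) / zeta < 0.9
  if (any(small)) out[small] <- fb_series(l, zeta, n, K[small])
  if (any(!small)) out[!small] <- fb_closed(l, zeta, n, K[!small])
  out
}

## spherical Bessel j_l(x) = sum_t coef * trig(x) / x^p
jl_terms <- function(l) {
  switch(as.character(l),
    "0" = list(c(p = 1, sin = 1, coef = 1)),
    "1" = list(c(p = 2, sin = 1, coef = 1), c(p = 1, sin = 0, coef = -1)),
    "2" = list(c(p = 3, sin = 1, coef = 3), c(p = 2, sin = 0, coef = -3),
               c(p = 1, sin = 1, coef = -1)),
    "3" = list(c(p = 4, sin = 1, coef = 15), c(p = 3, sin = 0, coef = -15),
               c(p = 2, sin = 1, coef = -6), c(p = 1, sin = 0, coef = 1)),
    "4" = list(c(p = 5, sin = 1, coef = 105), c(p = 4, sin = 0, coef = -105),
               c(p = 3, sin = 1, coef = -45), c(p = 2, sin = 0, coef = 10),
               c(p = 1, sin = 1, coef = 1))
  )
}

fb_closed <- function(l, zeta, n, K) {
  N <- exp((n + 3) * log(zeta) - lgamma(n + 3))
  acc <- numeric(length(K))
  zi <- complex(real = zeta, imaginary = -K)
  for (tm in jl_terms(l)) {
    q <- n + 2 - tm[["p"]]
    if (q < 0) stop("radial power n = ", n, " too small for l = ", l)
    Iq <- exp(lgamma(q + 1)) / zi^(q + 1)   # integral r^q e^{-zeta r} e^{iKr}
    val <- if (tm[["sin"]] == 1) Im(Iq) else Re(Iq)
    acc <- acc + tm[["coef"]] * val / K^tm[["p"]]
  }
  N * acc
}

fb_series <- function(l, zeta, n, K, tol = 1e-16, tmax = 40) {
  ## <j_l> = sum_t (-1)^t K^(l+2t) / (2^t t! (2l+2t+1)!!) <r^(l+2t)>
  ## with <r^m> = (n+2+m)! / ((n+2)! zeta^m)
  out <- numeric(length(K))
  for (t in 0:tmax) {
    m <- l + 2 * t
    ldc <- lgamma(n + 3 + m) - lgamma(n + 3) - m * log(zeta)
    ## (2l+2t+1)!! = (2l+2t+1)! / (2^(l+t) (l+t)!)
    ldf <- lgamma(2 * l + 2 * t + 2) - (l + t) * log(2) - lgamma(l + t + 1)
    term <- (-1)^t * exp(ldc - t * log(2) - lgamma(t + 1) - ldf) * K^m
    out <- out + term
    if (all(abs(term) <= tol * (abs(out) + 1e-300))) break
  }
  out
}

#' Spherical (IAM) atomic form factor
#'
#' Independent-atom-model form factor from the bundled Slater shell table:
#' the sum over shells of electron count times the shell's `<j_0>`
#' transform. Exactly `Z` at `s = 0`.
#'
#' @param element element symbol present in the bundled table.
#' @param s sin(theta)/lambda (1/angstrom), vectorized.
#' @return form factor in electrons.
#' @examples
#' iam_form_factor("C", 0)    # 6
#' iam_form_factor("H", 0.5)
#' @export
iam_form_factor <- function(element, s) {
  e <- element_entry(element)
  f <- core_form_factor(e, s) +
    e$valence$nel * fourier_bessel(0, density_zeta(e$valence$zeta), e$valence$n, s)
  f
}

core_form_factor <- function(e, s) {
  f <- numeric(length(s))
  for (sh in e$core)
    f <- f + sh$nel * fourier_bessel(0, density_zeta(sh$zeta), sh$n, s)
  f
}

valence_form_factor <- function(e, s, kappa = 1) {
  ## kappa-scaled valence density kappa^3 rho(kappa r) <-> f(s / kappa)
  fourier_bessel(0, density_zeta(e$valence$zeta), e$valence$n, s / kappa)
}

## real-space normalized Slater radial function R(r)
slater_radial <- function(zeta, n, r) {
  exp((n + 3) * log(zeta) - lgamma(n + 3) + n * log(pmax(r, 1e-300)) - zeta * r)
}
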