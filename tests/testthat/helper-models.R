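## shared toy fixtures, built in code

cubic10 <- unit_cell(10, 10, 10)

single_atom_model <- function(element = "C", xyz = c(0, 0, 0), u_iso = 0,
                              ...) {
  crystal_model(cubic10, space_group("P1"),
                list(mm_atom("A1", element, xyz, u_iso = u_iso, ...)))
}

## independent numerical quadrature of the Slater Fourier-Bessel transform
fb_quadrature <- function(l, zeta, n, s) {
  K <- 4 * pi * s
  jl <- function(l, x) {
    out <- numeric(length(x))
    sm <- x < 0.5
    if (any(sm)) {
      xs <- x[sm]; v <- 0
      for (t in 0:25)
        v <- v + (-1)^t * xs^(l + 2 * t) /
          (2^t * factorial(t) * prod(seq(2 * l + 2 * t + 1, 1, -2)))
      out[sm] <- v
    }
    xl <- x[!sm]
    if (length(xl)) out[!sm] <- switch(as.character(l),
      "0" = sin(xl) / xl,
      "1" = sin(xl) / xl^2 - cos(xl) / xl,
      "2" = (3 / xl^3 - 1 / xl) * sin(xl) - 3 * cos(xl) / xl^2,
      "3" = (15 / xl^4 - 6 / xl^2) * sin(xl) + (-15 / xl^3 + 1 / xl) * cos(xl),
      "4" = (105 / xl^5 - 45 / xl^3 + 1 / xl) * sin(xl) +
        (-105 / xl^4 + 10 / xl^2) * cos(xl))
    out
  }
  N <- zeta^(n + 3) / gamma(n + 3)
  vapply(K, function(k)
    stats::integrate(function(r) N * r^(n + 2) * exp(-zeta * r) * jl(l, k * r),
                     0, 60 / zeta, rel.tol = 1e-11,
                     subdivisions = 2000L)$value, numeric(1))
}
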