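test_that("IAM form factors: f(0) = Z, smooth monotone decay, frozen values", {
  expect_equal(iam_form_factor("C", 0), 6, tolerance = 0.01)
  expect_equal(iam_form_factor("H", 0), 1, tolerance = 0.01)
  expect_equal(iam_form_factor("Cl", 0), 17, tolerance = 0.01)
  s <- seq(0, 1.5, by = 0.01)
  for (el in c("H", "C", "N", "O", "F", "P", "S", "Si", "B", "Cl"))
    expect_true(all(diff(iam_form_factor(el, s)) < 0), label = el)
  ## frozen values from direct evaluation of the bundled Slater table
  expect_equal(iam_form_factor("C", 0.5), 1.681129, tolerance = 1e-5)
  expect_equal(iam_form_factor("H", 0.3), 0.251265, tolerance = 1e-5)
  expect_equal(iam_form_factor("O", 0.7), 1.652115, tolerance = 1e-5)
  expect_error(iam_form_factor("Xe", 0.1), "Slater table")
})

test_that("fourier_bessel agrees with adaptive quadrature of the Slater kernel", {
  expect_equal(fourier_bessel(0, 3, 2, 0), 1)
  expect_equal(fourier_bessel(2, 3, 2, 0), 0)
  s <- c(1e-4, 0.01, 0.05, 0.2, 0.4, 0.8, 1.2)
  for (l in 0:4) {
    n <- max(l, 2)
    got <- fourier_bessel(l, 6, n, s)
    want <- fb_quadrature(l, 6, n, s)
    expect_equal(got, want, tolerance = 1e-8, label = paste("l =", l))
  }
  ## (l = 1, zeta = 3, n = 2, s = 0.4) named example against quadrature
  expect_equal(fourier_bessel(1, 3, 2, 0.4), fb_quadrature(1, 3, 2, 0.4),
               tolerance = 1e-8)
})

test_that("multipole model reduces exactly to the IAM engine", {
  hkl <- as.matrix(expand.grid(0:4, -2:2, -2:2))
  hkl <- hkl[rowSums(abs(hkl)) > 0, ]
  a_iam <- mm_atom("A1", "N", c(0.13, 0.27, 0.41), u_iso = 0.015)
  m <- crystal_model(cubic10, space_group("P1"), list(a_iam))
  F1 <- structure_factor(m, hkl)
  s <- stol(cubic10, hkl)
  Texp <- displacement_factor(a_iam, hkl, cubic10)
  phase <- exp(2i * pi * as.numeric(hkl %*% a_iam$xyz))
  expect_equal(F1, iam_form_factor("N", s) * Texp * phase, tolerance = 1e-12)
  ## kappa = 2: valence term evaluated at s/2 (sharper density scatters
  ## farther out)
  a_k <- mm_atom("A1", "N", c(0, 0, 0), u_iso = 0, kappa = 2)
  mk <- crystal_model(cubic10, space_group("P1"), list(a_k))
  Fk <- Re(structure_factor(mk, hkl))
  e <- rcross:::element_entry("N")
  expect_equal(Fk,
               rcross:::core_form_factor(e, s) +
                 a_k$Pv * fourier_bessel(0, rcross:::density_zeta(e$valence$zeta),
                                         e$valence$n, s / 2),
               tolerance = 1e-12)
})

test_that("displacement factor: trivial limits and pdf Fourier oracle", {
  hkl <- rbind(c(1, 0, 0), c(2, 3, -1), c(5, 5, 5))
  a0 <- mm_atom("A1", "C", c(0, 0, 0), u_iso = 0)
  expect_equal(displacement_factor(a0, hkl, cubic10), rep(1 + 0i, 3))
  a1 <- mm_atom("A1", "C", c(0, 0, 0),
                U = c(0.02, 0.015, 0.01, 0.002, -0.001, 0.003))
  T1 <- displacement_factor(a1, hkl, cubic10)
  expect_equal(Im(T1), rep(0, 3))      # harmonic factor is real
  expect_true(all(Re(T1) > 0 & Re(T1) <= 1))
  ## anharmonic: T matches the numerical Fourier transform of the
  ## Gram-Charlier pdf
  a2 <- mm_atom("A1", "C", c(0, 0, 0), U = c(0.02, 0.025, 0.018, 0.003, 0, 0),
                C3 = c("C111" = 4e-4, "C123" = -2e-4, "C233" = 1.5e-4))
  hkl2 <- rbind(c(1, 0, 0), c(2, 1, 0), c(1, 2, 3))
  T_analytic <- displacement_factor(a2, hkl2, cubic10)
  T_pdf <- rcross:::pdf_fourier(a2, cubic10, hkl2, n = 81, extent = 7)
  expect_equal(T_analytic, T_pdf, tolerance = 1e-6)
  ## non-PSD U is projected with a warning
  bad <- mm_atom("A1", "C", c(0, 0, 0), U = c(-0.01, 0.02, 0.02, 0, 0, 0))
  expect_warning(displacement_factor(bad, hkl, cubic10), "PSD")
})

test_that("structure factors: electron count, closed forms, Friedel's law", {
  m <- single_atom_model("C")
  expect_equal(Re(structure_factor(m, c(0, 0, 0))), cell_electron_count(m))
  ## two identical atoms at +-x: F(h00) = 2 f cos(2 pi h x), purely real
  m2 <- crystal_model(cubic10, space_group("P1"),
                      list(mm_atom("C1", "C", c(0.15, 0, 0), u_iso = 0),
                           mm_atom("C2", "C", c(-0.15, 0, 0), u_iso = 0)))
  h <- cbind(1:5, 0, 0)
  F2 <- structure_factor(m2, h)
  expect_equal(Im(F2), rep(0, 5), tolerance = 1e-12)
  expect_equal(Re(F2),
               2 * iam_form_factor("C", stol(cubic10, h)) * cos(2 * pi * (1:5) * 0.15),
               tolerance = 1e-12)
  ## Friedel's law on random aspherical anharmonic models (no anomalous
  ## scattering)
  set.seed(2)
  for (rep in 1:5) {
    atoms <- lapply(1:3, function(i)
      mm_atom(paste0("A", i), sample(c("C", "N", "O"), 1), runif(3),
              U = c(runif(3, 0.005, 0.02), runif(3, -0.002, 0.002)),
              Plm = stats::setNames(runif(4, -0.3, 0.3),
                                    sample(multipole_names(4), 4)),
              C3 = stats::setNames(runif(2, -2e-4, 2e-4),
                                   sample(rcross:::C3_NAMES, 2)),
              kappa = runif(1, 0.9, 1.1), kappa_prime = runif(1, 0.9, 1.2)))
    mr <- crystal_model(cubic10, space_group("P1"), atoms)
    hr <- matrix(sample(-6:6, 60, TRUE), ncol = 3)
    hr <- hr[rowSums(abs(hr)) > 0, , drop = FALSE]
    expect_equal(Mod(structure_factor(mr, hr)),
                 Mod(structure_factor(mr, -hr)), tolerance = 1e-10)
  }
})

test_that("analytic derivative engine matches finite differences", {
  m <- make_toy_crystal("anharmonic_demo")
  hkl <- unique_reflections(m, 0.6)
  hkl <- hkl[seq(1, nrow(hkl), 5), ]
  geom <- rcross:::sf_geometry(m$cell, m$spacegroup, hkl)
  rows <- c("C1.U11", "C1.U12", "C1.C111", "C1.C112", "C1.Pv", "C1.P10",
            "C1.P20", "O1.U23", "O1.Pv", "O1.P10")
  de <- rcross:::sf_model_derivs(m, geom, rows)
  p0 <- full_params(m)
  for (r in rows) {
    d <- 1e-7
    p2 <- p0; p2[r] <- p2[r] + d
    fd <- (structure_factor(set_full_params(m, p2), hkl, geom) - de$F) / d
    expect_lt(max(Mod(fd - de$derivs[, r])) / max(Mod(de$derivs[, r])), 1e-4)
  }
})

test_that("aspherical dipole term matches the 3-D grid Fourier transform", {
  ## compact version of the grid-FT oracle (the acceptance suite runs the
  ## full-resolution variant): one dipole-deformed C atom in P1
  uc <- unit_cell(4.2, 4.2, 4.2)
  m <- crystal_model(uc, space_group("P1"),
                     list(mm_atom("C1", "C", c(0.31, 0.42, 0.27), u_iso = 0,
                                  Plm = c("P10" = 0.25, "P20" = 0.1))))
  n <- 96
  rho <- sample_cell_density(m, n, rcut = 6)
  Fg <- fft(rho, inverse = TRUE) * uc$volume / length(rho)
  hkl <- as.matrix(expand.grid(-4:4, -4:4, -4:4))
  hkl <- hkl[stol(uc, hkl) > 0 & stol(uc, hkl) <= 0.6, ]
  Fa <- structure_factor(m, hkl)
  idx <- (hkl %% n) + 1
  Fgv <- Fg[cbind(idx[, 1], idx[, 2], idx[, 3])]
  expect_lt(max(Mod(Fgv - Fa) / Mod(Fa)), 0.005)
})
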