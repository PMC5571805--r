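test_that("unit cell metric and reciprocal metric are mutually consistent", {
  uc <- unit_cell(5.4, 6.1, 7.3, 83, 99, 105)
  expect_equal(uc$G %*% uc$Gstar, diag(3), tolerance = 1e-10)
  expect_gt(uc$volume, 0)
  expect_error(unit_cell(-1, 2, 3), "positive|> 0")
  expect_error(unit_cell(5, 5, 5, alpha = 181), "angles")
})

test_that("symmetry operators parse, compose and close as a group", {
  op <- parse_symop("-x+1/2, y, z+1/2")
  expect_equal(op$R, matrix(c(-1, 0, 0, 0, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE))
  expect_equal(op$t, c(0.5, 0, 0.5))
  expect_equal(parse_symop(symop_to_string(op)), op)
  for (sym in c("P-1", "P21/c", "Pnma")) {
    sg <- space_group(sym)
    ## closed: composing any two ops stays in the set
    keys <- vapply(sg$ops, rcross:::op_key, character(1))
    for (a in sg$ops[1:min(4, length(sg$ops))]) for (b in sg$ops) {
      expect_true(rcross:::op_key(rcross:::compose_op(a, b)) %in% keys)
    }
    expect_true(any(vapply(sg$ops, function(o) all(o$R == diag(3)), logical(1))))
  }
  expect_true(space_group("P-1")$centrosymmetric)
  expect_false(space_group("Pm")$centrosymmetric)
  expect_error(space_group("Xx99"), "unknown space-group")
})

test_that("allowed multipoles match numerical invariance of the harmonics", {
  all_none <- allowed_multipoles("none", 4)
  expect_length(all_none, 25)          # 25 pole populations incl. monopole
  expect_true(all(all_none))

  cyl <- allowed_multipoles("cyl", 4)
  expect_identical(names(cyl)[cyl], c("P00", "P10", "P20", "P30", "P40"))

  mm2 <- allowed_multipoles("mm2", 4)
  ## independent check: explicit invariance under the two mirrors at 100
  ## random directions
  set.seed(42)
  u <- matrix(rnorm(300), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  Y <- real_spherical_harmonics(u, names(mm2))
  inv <- rep(TRUE, length(mm2))
  for (R in list(diag(c(-1, 1, 1)), diag(c(1, -1, 1)))) {
    Yr <- real_spherical_harmonics(u %*% t(R), names(mm2))
    inv <- inv & (apply(abs(Yr - Y), 2, max) < 1e-8)
  }
  expect_identical(unname(inv), unname(mm2))
  ## random rotations about z leave exactly the cylindrical set invariant
  set.seed(7)
  keep <- rep(TRUE, 25)
  for (phi in runif(100, 0, 2 * pi)) {
    R <- rcross:::rot_z(phi)
    Yr <- real_spherical_harmonics(u %*% t(R), names(cyl))
    keep <- keep & (apply(abs(Yr - Y), 2, max) < 1e-8)
  }
  expect_identical(unname(keep), unname(allowed_multipoles("cyl", 4)))

  expect_error(allowed_multipoles("frobnitz", 4), "valid codes")
  expect_error(allowed_multipoles("m", 7), "l_max")
})

test_that("real spherical harmonics are orthonormal on the sphere", {
  ## exact quadrature: polynomials of degree <= 8 integrate exactly on a
  ## fine theta-phi product grid with cos(theta) midpoint weights
  nth <- 500; nph <- 72
  ct <- seq(-1 + 1 / nth, 1 - 1 / nth, length.out = nth)
  ph <- seq(0, 2 * pi * (1 - 1 / nph), length.out = nph)
  g <- expand.grid(ct = ct, ph = ph)
  st <- sqrt(1 - g$ct^2)
  u <- cbind(st * cos(g$ph), st * sin(g$ph), g$ct)
  w <- (2 / nth) * (2 * pi / nph)
  Y <- real_spherical_harmonics(u, multipole_names(4, include_monopole = TRUE))
  Gram <- crossprod(Y * sqrt(w))
  expect_equal(unname(diag(Gram)), rep(1, 25), tolerance = 1e-3)
  expect_lt(max(abs(Gram - diag(25))), 1e-3)
})

test_that("site-symmetry constraints reproduce the mirror and inversion cases", {
  uc <- unit_cell(6, 7, 8)
  ## general position: no constraints
  mg <- crystal_model(uc, space_group("Pnma"),
                      list(mm_atom("C1", "C", c(0.11, 0.07, 0.23))))
  sc <- site_symmetry_constraints(mg, "C1")
  expect_equal(sc$order, 1)
  expect_length(sc$zero, 0)
  expect_length(sc$fixed, 0)

  ## atom on the Pnma mirror plane y = 1/4: C112 (and every component with
  ## an odd count of the mirror-normal index) is forced to zero
  mp <- crystal_model(uc, space_group("Pnma"),
                      list(mm_atom("P1", "P", c(0.1, 0.25, 0.3),
                                   occupancy = 0.25, use_c3 = TRUE)))
  scp <- site_symmetry_constraints(mp, "P1")
  expect_equal(scp$order, 2)
  expect_true(all(c("C112", "C222", "C123", "C233") %in% scp$zero))
  expect_true(all(c("U12", "U23") %in% scp$zero))
  expect_equal(scp$fixed[["y"]], 0.25)

  ## inversion centre: all odd-l poles and all ten C3 components vanish
  mi <- crystal_model(uc, space_group("P-1"),
                      list(mm_atom("C1", "C", c(0, 0, 0), occupancy = 0.5,
                                   use_c3 = TRUE)))
  sci <- site_symmetry_constraints(mi, "C1")
  expect_true(all(rcross:::C3_NAMES %in% sci$zero))
  odd_l <- grep("^P[13]", multipole_names(4), value = TRUE)
  expect_true(all(odd_l %in% sci$zero))
  ## brute-force oracle: the pdf/density of the invariant parameters must
  ## be even; every surviving pole is an even-l harmonic
  kept <- setdiff(multipole_names(4), sci$zero)
  expect_true(all(substr(kept, 2, 2) %in% c("2", "4")))
})

test_that("pack/unpack: lengths, ties and exact round trips", {
  uc <- unit_cell(6, 7, 8)
  m1 <- crystal_model(uc, space_group("P1"),
                      list(mm_atom("C1", "C", c(0.1, 0.2, 0.3))))
  cm1 <- constraint_map(m1)
  expect_length(pack_parameters(m1, cm1, classes = "xyz"), 3)

  ## two chemically tied atoms: one monopole free parameter drives both
  m2 <- crystal_model(uc, space_group("P1"),
                      list(mm_atom("C1", "C", c(0.1, 0.2, 0.3)),
                           mm_atom("C2", "C", c(0.6, 0.7, 0.8))),
                      ties = list(c("C1", "C2")))
  cm2 <- constraint_map(m2)
  mono <- pack_parameters(m2, cm2, classes = "M")
  expect_length(mono, 1)
  m2b <- unpack_parameters(stats::setNames(4.37, names(mono)), m2, cm2)
  expect_equal(m2b$atoms$C1$Pv, 4.37)
  expect_equal(m2b$atoms$C2$Pv, 4.37)

  ## property: random conforming models round-trip bit-identically
  for (seed in 1:20) {
    set.seed(seed)
    mm <- make_toy_crystal(sample(c("centro_simple", "overfit_demo",
                                    "mirror_special"), 1))
    mm <- shake(mm, amplitude = 0.01, seed = seed)
    cm <- constraint_map(mm)
    p0 <- full_params(mm)
    mm2 <- unpack_parameters(pack_parameters(mm, cm), mm, cm)
    expect_identical(full_params(mm2), p0)
  }

  ## selection of a forbidden parameter is rejected
  m3 <- make_toy_crystal("mirror_special")
  cm3 <- constraint_map(m3)
  expect_error(pack_parameters(m3, cm3, params = "F1.C112"),
               "fixed or forbidden")
})

test_that("constraint application is idempotent and rank-consistent", {
  m <- make_toy_crystal("mirror_special")
  cm <- constraint_map(m)
  ## perturb the model off the constraint manifold, then project twice
  m$atoms$F1$xyz[2] <- 0.013
  m$atoms$F1$C3["C112"] <- 4e-4
  p1 <- full_params(apply_constraints(m, cm))
  p2 <- full_params(apply_constraints(apply_constraints(m, cm), cm))
  expect_identical(p1, p2)
  expect_equal(unname(p1["F1.y"]), 0)
  expect_equal(unname(p1["F1.C112"]), 0)
  ## free count = full count - number of independent constraints:
  ## A has full column rank equal to the free count
  expect_equal(qr(cm$A)$rank, length(cm$free_names))
})

test_that("model YAML config round-trips", {
  m <- make_toy_crystal("overfit_demo")
  path <- tempfile(fileext = ".yaml")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(full_params(m2), full_params(m), tolerance = 1e-9)
  expect_equal(length(m2$ties), length(m$ties))
  expect_equal(m2$atoms$C2$local_symmetry, "cyl")
  expect_equal(m2$cell$volume, m$cell$volume, tolerance = 1e-9)
})
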