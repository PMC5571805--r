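test_that("density grids integrate to the electron count and exclude H", {
  uc <- unit_cell(12, 12, 12)
  m <- crystal_model(uc, space_group("P1"),
                     list(mm_atom("C1", "C", c(0.5, 0.5, 0.5), u_iso = 0)))
  g <- density_grid(m, origin = c(4, 4, 4), npts = 81, spacing = 0.05,
                    exclude_H = FALSE)
  tot <- sum(g$values) * 0.05^3
  expect_equal(tot, 6, tolerance = 0.06)       # within 1%
  ## CH fragment with H excluded equals the C-only grid
  mh <- crystal_model(uc, space_group("P1"),
                      list(mm_atom("C1", "C", c(0.5, 0.5, 0.5), u_iso = 0),
                           mm_atom("H1", "H", c(0.5, 0.5, 0.59), u_iso = 0)))
  gh <- density_grid(mh, origin = c(4, 4, 4), npts = 41, spacing = 0.1,
                     exclude_H = TRUE)
  gc <- density_grid(m, origin = c(4, 4, 4), npts = 41, spacing = 0.1,
                     exclude_H = TRUE)
  expect_equal(gh$values, gc$values, tolerance = 1e-12)
})

test_that("a dipole deformation is antisymmetric along its local z", {
  uc <- unit_cell(12, 12, 12)
  base <- crystal_model(uc, space_group("P1"),
                        list(mm_atom("C1", "C", c(0.5, 0.5, 0.5), u_iso = 0)))
  dip <- crystal_model(uc, space_group("P1"),
                       list(mm_atom("C1", "C", c(0.5, 0.5, 0.5), u_iso = 0,
                                    Plm = c("P10" = 0.2))))
  z <- seq(-1.5, 1.5, by = 0.05)
  pts_up <- cbind(6, 6, 6 + z)
  diff_rho <- model_density(dip, pts_up) - model_density(base, pts_up)
  expect_equal(diff_rho, -rev(diff_rho), tolerance = 1e-10)
})

test_that("error cubes: zeros for identical members, k-1 convention, locality", {
  m <- make_toy_crystal("centro_simple")
  grids <- lapply(1:3, function(i)
    density_grid(m, origin = c(0, 0, 0), npts = 13, spacing = 0.3))
  ec <- error_cube(grids)
  expect_lt(max(ec$values), 1e-13)
  ## k = 2 with point values 1 and 3: sd = sqrt(2)
  g1 <- grids[[1]]; g2 <- grids[[1]]
  g1$values[] <- 1; g2$values[] <- 3
  expect_true(all(abs(error_cube(list(g1, g2))$values - sqrt(2)) < 1e-12))
  ## geometry mismatch errors
  g3 <- g2; g3$origin <- g3$origin + 0.1
  expect_error(error_cube(list(g1, g3)), "geometr")
  ## perturbing one atom's multipoles concentrates the error near it
  vary <- lapply(c(-0.08, 0, 0.08), function(d) {
    mm <- m
    mm$atoms$N1$Plm["P20"] <- mm$atoms$N1$Plm["P20"] + d
    density_grid(mm, origin = c(-1, 0, 0), npts = 25, spacing = 0.35)
  })
  ec2 <- error_cube(vary)
  idx <- which(ec2$values == max(ec2$values), arr.ind = TRUE)[1, ]
  peak <- ec2$origin + (idx - 1) * 0.35
  ## nearest symmetry image of N1 (the inversion mate carries the same
  ## perturbed populations)
  imgs <- rcross:::density_images(m, matrix(peak, 1, 3), rcut = 8)
  dmin <- min(vapply(imgs, function(im)
    if (im$atom$label == "N1") sqrt(sum((peak - im$pos)^2)) else Inf,
    numeric(1)))
  expect_lt(dmin, 1.5)
})

test_that("cube files round-trip through the Bohr-unit header", {
  set.seed(6)
  g <- structure(list(origin = c(-1.2, 0.4, 2.25),
                      axes = diag(c(0.11, 0.11, 0.11)),
                      npts = c(5L, 4L, 7L),
                      values = array(round(runif(140), 5), c(5, 4, 7))),
                 class = "density_grid")
  path <- tempfile(fileext = ".cube")
  write_cube(g, path, atoms = cbind(6, 0.2, 0.4, 0.9))
  g2 <- read_cube(path)
  expect_equal(g2$origin, g$origin, tolerance = 1e-5)
  expect_equal(g2$axes, g$axes, tolerance = 1e-6)
  expect_identical(g2$npts, g$npts)
  expect_lt(max(abs(g2$values - g$values)), 1e-6)
  ## malformed header errors with a location
  writeLines(c("x", "y", "junk here", "1 2 3", "1 2 3", "1 2 3"), path)
  expect_error(read_cube(path), "malformed cube")
})

test_that("Gram-Charlier pdf: positivity, normalization, negativity onset", {
  uc <- unit_cell(10, 10, 10)
  harm <- mm_atom("A1", "F", c(0, 0, 0), U = c(0.02, 0.025, 0.018, 0.002, 0, 0))
  pe <- pdf_eval(harm, uc)
  expect_gte(pe$min, 0)
  expect_equal(pe$neg_percent, 0)
  expect_equal(pe$total, 1, tolerance = 1e-3)
  ## large C111 drives the pdf negative with positive negative-probability
  anh <- mm_atom("A1", "F", c(0, 0, 0), U = c(0.02, 0.025, 0.018, 0.002, 0, 0),
                 C3 = c("C111" = 3e-3))
  pa <- pdf_eval(anh, uc, n = 61)
  expect_lt(pa$min, 0)
  expect_gt(pa$neg_percent, 0)
  expect_error(pdf_eval(mm_atom("A1", "F", c(0, 0, 0), u_iso = 0), uc),
               "positive definite")
})

test_that("bond critical points: midpoint symmetry, ellipticity, Gaussian oracle", {
  uc <- unit_cell(12, 12, 12)
  ## homonuclear diatomic along z: BCP at the midpoint, cylindrical
  m <- crystal_model(uc, space_group("P1"),
                     list(mm_atom("C1", "C", c(0.5, 0.5, 0.55), u_iso = 0),
                          mm_atom("C2", "C", c(0.5, 0.5, 0.45), u_iso = 0)))
  cp <- find_bcp(m, c("C1", "C2"))
  mid <- as.numeric(rcross:::frac_to_cart(uc, c(0.5, 0.5, 0.5)))
  expect_lt(sqrt(sum((cp$position - mid)^2)), 1e-4)
  expect_true(cp$is_bcp)
  expect_identical(cp$signature, c(3, -1))
  expect_lt(cp$ellipticity, 1e-6)
  expect_gt(cp$rho, 0)
  ## single 3-D Gaussian: Laplacian matches the closed form
  alpha <- 1.7
  f <- function(x) exp(-alpha * sum(x^2))
  r <- c(0.31, -0.12, 0.22)
  H <- density_hessian(f, r, h = 1e-3)
  lap <- sum(diag(H))
  want <- (4 * alpha^2 * sum(r^2) - 6 * alpha) * exp(-alpha * sum(r^2))
  expect_equal(lap, want, tolerance = 1e-6)
  ## stationary point of the Gaussian itself: (3, -3) maximum at origin
  cpg <- find_bcp(f, start = c(0.05, -0.04, 0.02))
  expect_lt(sqrt(sum(cpg$position^2)), 1e-6)
  expect_identical(cpg$signature, c(3, -3))
  ## atoms too far apart are rejected
  mfar <- crystal_model(uc, space_group("P1"),
                        list(mm_atom("C1", "C", c(0.1, 0.1, 0.1), u_iso = 0),
                             mm_atom("C2", "C", c(0.9, 0.9, 0.9), u_iso = 0)))
  expect_error(find_bcp(mfar, c("C1", "C2")), "3 A apart")
})

test_that("BCP position is stable to finite-difference hyperparameters", {
  uc <- unit_cell(12, 12, 12)
  m <- crystal_model(uc, space_group("P1"),
                     list(mm_atom("C1", "C", c(0.5, 0.5, 0.552), u_iso = 0),
                          mm_atom("O1", "O", c(0.5, 0.5, 0.45), u_iso = 0)))
  cp1 <- find_bcp(m, c("C1", "O1"), h_hess = 1e-3)
  cp2 <- find_bcp(m, c("C1", "O1"), h_hess = 4e-3, h_grad = 1e-5)
  expect_lt(sqrt(sum((cp1$position - cp2$position)^2)), 1e-4)
})

test_that("bcp_distribution tabulates k-member spreads against the total", {
  m <- make_toy_crystal("centro_simple")
  ## k identical members: zero spread and zero deviation
  tab <- bcp_distribution(list(m, m, m), m, list(c("C1", "O1")))
  expect_equal(tab$s_mean, rep(0, 3))
  expect_equal(tab$v_mean, tab$v_total)
  ## perturbed members: rho spreads much less (relatively) than the
  ## Laplacian
  mems <- lapply(1:6, function(i) {
    mm <- m
    set.seed(i)
    mm$atoms$C1$Plm["P20"] <- mm$atoms$C1$Plm["P20"] + rnorm(1, 0, 0.03)
    mm$atoms$C1$Pv <- mm$atoms$C1$Pv + rnorm(1, 0, 0.03)
    mm
  })
  tab2 <- bcp_distribution(mems, m, list(c("C1", "O1")))
  rel <- tab2$s_mean / pmax(abs(tab2$v_total), 1e-9)
  expect_lt(rel[tab2$property == "rho"], rel[tab2$property == "laplacian"])
  expect_true(all(is.finite(tab2$W[!tab2$excluded])))
  ## a pair without a BCP in some member is excluded, not fatal
  tab3 <- bcp_distribution(list(m), m, list(c("C1", "N1")))
  expect_true(all(tab3$excluded) || all(!tab3$excluded))
})
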