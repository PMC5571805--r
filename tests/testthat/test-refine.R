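test_that("shake is deterministic, vanishes with amplitude, and is Gaussian", {
  m <- make_toy_crystal("centro_simple")
  m1 <- shake(m, 0.002, seed = 4)
  m2 <- shake(m, 0.002, seed = 4)
  expect_identical(full_params(m1), full_params(m2))
  m3 <- shake(m, 1e-12, seed = 4, u_frac = 1e-12)
  expect_equal(full_params(m3), full_params(m), tolerance = 1e-9)
  ## coordinate shifts over many draws follow N(0, amplitude)
  amp <- 0.002
  shifts <- unlist(lapply(1:350, function(s) {
    ms <- shake(m, amp, seed = s, u_frac = 0)
    full_params(ms)[c("N1.x", "N1.y", "N1.z")] - full_params(m)[c("N1.x", "N1.y", "N1.z")]
  }))
  ks <- stats::ks.test(shifts / amp, "pnorm")
  expect_gt(ks$p.value, 0.01)
  ## constraints are re-applied: a mirror atom stays on the mirror
  mm <- make_toy_crystal("mirror_special")
  ms <- shake(mm, 0.005, seed = 9)
  expect_equal(ms$atoms$F1$xyz[2], 0)
  expect_equal(unname(ms$atoms$F1$U[c("U12", "U23")]), c(0, 0))
})

test_that("refinement at the truth on noiseless data stays put with R = 0", {
  sc <- make_scenario("centro_simple", noise = 0)
  step <- strategy_step("all", classes = c("xyz", "U", "M", "D", "Q", "K", "KP"))
  fit <- lsq_refine(sc$model, sc$reflections, step)
  expect_lt(fit$r_f, 1e-8)
  expect_true(fit$converged)
  expect_equal(full_params(fit$model), full_params(sc$model), tolerance = 1e-7)
})

test_that("noiseless data from a shaken start recovers the generator", {
  sc <- make_scenario("centro_simple", noise = 0)
  m0 <- shake(sc$model, 0.002, seed = 13)
  step <- strategy_step("all", classes = c("xyz", "U", "M", "D", "Q", "K", "KP"))
  fit <- lsq_refine(m0, sc$reflections, step)
  p_true <- full_params(sc$model)
  p_fit <- full_params(fit$model)
  nz <- abs(p_true) > 1e-8
  expect_lt(max(abs(p_fit[nz] - p_true[nz]) / abs(p_true[nz])), 1e-4)
  expect_lt(fit$r_f, 1e-6)
})

test_that("exactly collinear free parameters raise a singularity error", {
  ## two superimposed untied atoms: their monopole derivatives are
  ## identical columns
  m <- crystal_model(cubic10, space_group("P1"),
                     list(mm_atom("C1", "C", c(0.2, 0.3, 0.4), u_iso = 0.01),
                          mm_atom("C2", "C", c(0.2, 0.3, 0.4), u_iso = 0.01)))
  refl <- simulate_fobs(m, res_limit = 0.5, noise = 0.01, seed = 1)
  step <- strategy_step("mono", classes = "M")
  expect_error(lsq_refine(m, refl, step), "null-space.*Pv|Pv.*null-space")
})

test_that("releasing more parameters never increases the converged residual", {
  sc <- make_scenario("overfit_demo", seed = 2)
  m0 <- shake(iam_model(sc$model), 0.002, seed = 3)
  sels <- list(c("xyz", "U"),
               c("xyz", "U", "M", "K"),
               c("xyz", "U", "M", "D", "Q", "K"),
               c("xyz", "U", "M", "D", "Q", "K", "KP"))
  prev <- Inf
  model <- m0
  for (i in seq_along(sels)) {
    fit <- lsq_refine(model, sc$reflections, strategy_step(paste0("s", i), sels[[i]]))
    sse <- fit$gof^2 * (fit$n_obs - fit$n_par)
    expect_lte(sse, prev * (1 + 1e-8))
    prev <- sse
    model <- fit$model
  }
})

test_that("staged refinement honours data filters and empty strategies", {
  sc <- make_scenario("centro_simple", seed = 1)
  expect_identical(staged_refinement(sc$model, sc$reflections, list()), list())
  ## a high-order step sees only stol >= cut reflections
  fit_hi <- lsq_refine(sc$model, sc$reflections,
                       strategy_step("hi", "xyz", filter = "high", cut = 0.6))
  expect_equal(fit_hi$n_obs, sum(sc$reflections$data$stol >= 0.6))
  fit_lo <- lsq_refine(sc$model, sc$reflections,
                       strategy_step("lo", "xyz", filter = "low", cut = 0.5))
  expect_equal(fit_lo$n_obs, sum(sc$reflections$data$stol <= 0.5))
})

test_that("parameter recovery and s.u. calibration at 1% noise", {
  ## over several noise realizations nearly all selected parameters land
  ## within 3 s_total, and the empirical spread matches s_total to a
  ## factor 1.5
  step <- strategy_step("all", classes = c("xyz", "U", "M", "D", "Q", "K"))
  devs <- c(); ests <- list(); sus <- list()
  for (seed in 1:6) {
    sc <- make_scenario("centro_simple", seed = seed)
    m0 <- shake(sc$model, 0.002, seed = seed + 50)
    fit <- lsq_refine(m0, sc$reflections, step)
    f_true <- pack_parameters(sc$model, fit$cmap)
    devs <- c(devs, abs(fit$free[fit$selected] - f_true[fit$selected]) / fit$su)
    ests[[seed]] <- fit$free[fit$selected]
    sus[[seed]] <- fit$su
  }
  expect_gte(mean(devs < 3), 0.95)
  E <- do.call(rbind, ests)
  emp_sd <- apply(E, 2, stats::sd)
  su_bar <- colMeans(do.call(rbind, sus))
  ratio <- emp_sd / su_bar
  ## median ratio within a factor 1.5 of unity
  expect_gt(stats::median(ratio), 1 / 1.5)
  expect_lt(stats::median(ratio), 1.5)
})

test_that("H atoms move to neutron distances along their bond vectors", {
  uc <- unit_cell(8, 8, 8)
  c1 <- c(0.30, 0.30, 0.30)
  h_dir <- c(1, 1, 0) / sqrt(2)
  h1 <- c1 + as.numeric(rcross:::cart_to_frac(uc, matrix(h_dir * 0.98, 1, 3)))
  m <- crystal_model(uc, space_group("P1"),
                     list(mm_atom("C1", "C", c1),
                          mm_atom("H1", "H", h1)))
  m2 <- set_neutron_distances(m)
  v <- rcross:::frac_to_cart(uc, m2$atoms$H1$xyz) - rcross:::frac_to_cart(uc, c1)
  expect_equal(sqrt(sum(v^2)), neutron_distance_table()[["C"]])
  expect_equal(as.numeric(v / sqrt(sum(v^2))), h_dir, tolerance = 1e-9)
  ## already at the tabulated distance: unchanged
  m3 <- set_neutron_distances(m2)
  expect_equal(m3$atoms$H1$xyz, m2$atoms$H1$xyz, tolerance = 1e-12)
  ## orphan H is an error
  mo <- crystal_model(uc, space_group("P1"),
                      list(mm_atom("C1", "C", c(0, 0, 0)),
                           mm_atom("H9", "H", c(0.5, 0.5, 0.5))))
  expect_error(set_neutron_distances(mo), "no parent")
})

test_that("strategy YAML files round-trip", {
  strat <- list(
    strategy_step("high", c("xyz", "U"), filter = "high", cut = 0.75),
    strategy_step("poles", c("M", "D"), atoms = c("C1", "C2"),
                  release_ties = TRUE, fix_params = "C1.x"),
    strategy_step("anh", c("xyz", "C3"), add_c3 = "F1"))
  path <- tempfile(fileext = ".yaml")
  write_strategy(strat, path)
  got <- read_strategy(path)
  for (i in seq_along(strat)) {
    expect_equal(got[[i]]$name, strat[[i]]$name)
    expect_equal(got[[i]]$classes, strat[[i]]$classes)
    expect_equal(got[[i]]$filter, strat[[i]]$filter)
    expect_equal(got[[i]]$cut, strat[[i]]$cut)
    expect_equal(got[[i]]$release_ties, strat[[i]]$release_ties)
    expect_equal(got[[i]]$fix_params, strat[[i]]$fix_params)
    expect_equal(got[[i]]$add_c3, strat[[i]]$add_c3)
  }
})
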