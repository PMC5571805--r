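## Synthetic fixtures: toy crystals with known ground truth, simulated
## observations and the failure scenarios the diagnostics are designed to
## catch. Every scenario is fully reproducible from (name, seed).
##
## Default study conditions: 1% multiplicative Gaussian noise on F^2, 20
## test sets, resolution limits of 0.8-1.1 1/A depending on scenario (all
## at or above the 0.8 1/A floor a multipole model needs).

SCENARIO_NAMES <- c("centro_simple", "noncentro_pair", "mirror_special",
                    "overfit_demo", "anharmonic_demo", "outlier_demo")

## place atom `label` at distance `d` (angstrom) from `from` along the
## Cartesian direction `dir`
place_bonded <- function(cell, from_xyz, dir, d) {
  dir <- dir / sqrt(sum(dir^2))
  as.numeric(from_xyz + cart_to_frac(cell, matrix(dir * d, 1, 3)))
}

#' Build a toy crystal with known ground truth
#'
#' Scenarios:
#' \describe{
#'   \item{centro_simple}{P-1; C, O, N with modest multipoles; the
#'     parameter-recovery workhorse.}
#'   \item{noncentro_pair}{P1 with acentric content, exercising Friedel
#'     pairing.}
#'   \item{mirror_special}{Pm with an anharmonic F atom on the mirror
#'     (site multiplicity 2, occupancy 1/2); the mirror-forbidden C3
#'     components are exactly zero in the ground truth.}
#'   \item{overfit_demo}{P-1 with two chemically equivalent C-O groups:
#'     tied populations and cylindrical local symmetry, so releasing those
#'     constraints is pure overparameterization.}
#'   \item{anharmonic_demo}{P-1 with one genuinely anharmonic C atom whose
#'     U satisfies Kuhs' rule at the scenario resolution.}
#'   \item{outlier_demo}{the centro_simple crystal; pair with
#'     [inject_outliers()] on its simulated data.}
#' }
#'
#' @param scenario one of the names above.
#' @return a [crystal_model()]; attribute `"resolution"` carries the
#'   scenario's resolution limit (sin(theta)/lambda, 1/angstrom) and
#'   attribute `"noise"` its noise fraction.
#' @export
make_toy_crystal <- function(scenario) {
  scenario <- match.arg(scenario, SCENARIO_NAMES)
  m <- switch(scenario,
    centro_simple = , outlier_demo = {
      cell <- unit_cell(5.4, 5.9, 6.3, 90, 98, 90)
      c1 <- c(0.130, 0.180, 0.220)
      o1 <- place_bonded(cell, c1, c(0.8, 0.5, 0.3), 1.23)
      n1 <- c(0.180, 0.560, 0.420)
      atoms <- list(
        mm_atom("C1", "C", c1, U = c(0.012, 0.015, 0.011, 0.002, 0.001, -0.001),
                Pv = 4.15, Plm = c("P10" = 0.25, "P20" = 0.12),
                kappa = 0.99, kappa_prime = 1.05,
                local_axes = list(ref1 = "O1"), local_symmetry = "cyl"),
        mm_atom("O1", "O", o1, U = c(0.016, 0.014, 0.017, -0.002, 0.002, 0.001),
                Pv = 6.10, Plm = c("P10" = -0.10, "P20" = 0.08),
                kappa = 0.985, kappa_prime = 1.02,
                local_axes = list(ref1 = "C1"), local_symmetry = "cyl"),
        mm_atom("N1", "N", n1, U = c(0.013, 0.012, 0.014, 0.001, -0.002, 0.002),
                Pv = 5.05, Plm = c("P10" = 0.10, "P11+" = 0.06, "P20" = 0.05),
                kappa = 0.995, kappa_prime = 1.00),
        mm_atom("F1", "F", c(0.620, 0.300, 0.750),
                U = c(0.018, 0.020, 0.017, 0.002, -0.001, 0.001),
                Pv = 7.02, Plm = c("P10" = -0.06, "P20" = 0.04),
                kappa = 0.99, kappa_prime = 1.0),
        mm_atom("C2", "C", c(0.560, 0.820, 0.080),
                U = c(0.014, 0.013, 0.015, -0.001, 0.002, 0.001),
                Pv = 4.05, Plm = c("P20" = 0.09, "P22+" = 0.05),
                kappa = 0.995, kappa_prime = 1.02))
      mod <- crystal_model(cell, space_group("P-1"), atoms)
      attr(mod, "resolution") <- 0.9
      mod
    },
    noncentro_pair = {
      cell <- unit_cell(5.2, 5.7, 6.1, 90, 96, 90)
      c1 <- c(0.150, 0.220, 0.260)
      o1 <- place_bonded(cell, c1, c(0.7, 0.6, 0.4), 1.23)
      n1 <- c(0.520, 0.610, 0.350)
      atoms <- list(
        mm_atom("C1", "C", c1, U = c(0.013, 0.014, 0.012, 0.001, 0.002, -0.001),
                Pv = 4.2, Plm = c("P10" = 0.22, "P20" = 0.10),
                kappa = 0.99, kappa_prime = 1.04,
                local_axes = list(ref1 = "O1"), local_symmetry = "cyl"),
        mm_atom("O1", "O", o1, U = c(0.015, 0.016, 0.014, -0.001, 0.001, 0.002),
                Pv = 6.05, Plm = c("P10" = -0.12, "P20" = 0.07),
                kappa = 0.99, kappa_prime = 1.02,
                local_axes = list(ref1 = "C1"), local_symmetry = "cyl"),
        mm_atom("N1", "N", n1, U = c(0.012, 0.013, 0.015, 0.002, -0.001, 0.001),
                Pv = 5.1, Plm = c("P10" = 0.09, "P21+" = 0.05),
                kappa = 1.0, kappa_prime = 1.0),
        mm_atom("F1", "F", c(0.600, 0.280, 0.720),
                U = c(0.017, 0.019, 0.016, 0.001, 0.002, -0.001),
                Pv = 7.03, Plm = c("P10" = -0.05, "P20" = 0.04),
                kappa = 0.99, kappa_prime = 1.0))
      mod <- crystal_model(cell, space_group("P1"), atoms)
      attr(mod, "resolution") <- 0.9
      mod
    },
    mirror_special = {
      cell <- unit_cell(5.6, 5.9, 6.2, 90, 102, 90)
      f1 <- c(0.280, 0.000, 0.340)          # on the mirror y = 0
      c1 <- place_bonded(cell, f1, c(0.9, 0.0, 0.44), 1.35)
      o1 <- c(0.640, 0.260, 0.610)
      atoms <- list(
        mm_atom("F1", "F", f1, U = c(0.020, 0.022, 0.019, 0, 0.003, 0),
                occupancy = 0.5,
                Pv = 7.05, Plm = c("P10" = -0.08),
                kappa = 0.99, kappa_prime = 1.0,
                local_axes = list(ref1 = "C1"), local_symmetry = "cyl",
                C3 = c("C111" = 1.0e-5, "C333" = 6e-6, "C113" = 4e-6),
                use_c3 = TRUE),
        mm_atom("C1", "C", c1, U = c(0.013, 0.014, 0.012, 0, 0.002, 0),
                occupancy = 0.5,
                Pv = 4.1, Plm = c("P10" = 0.20, "P20" = 0.10),
                kappa = 0.99, kappa_prime = 1.03,
                local_axes = list(ref1 = "F1"), local_symmetry = "cyl"),
        mm_atom("O1", "O", o1, U = c(0.015, 0.016, 0.014, 0.002, 0.001, -0.002),
                Pv = 6.1, Plm = c("P10" = -0.09, "P20" = 0.06),
                kappa = 0.99, kappa_prime = 1.0),
        mm_atom("N1", "N", c(0.150, 0.250, 0.850),
                U = c(0.014, 0.015, 0.013, 0.001, 0.002, 0.001),
                Pv = 5.05, Plm = c("P10" = 0.08, "P20" = 0.05),
                kappa = 0.995, kappa_prime = 1.0))
      mod <- crystal_model(cell, space_group("Pm"), atoms)
      attr(mod, "resolution") <- 1.0
      mod
    },
    overfit_demo = {
      cell <- unit_cell(5.6, 6.1, 6.6, 90, 97, 90)
      c1 <- c(0.140, 0.190, 0.210)
      o1 <- place_bonded(cell, c1, c(0.8, 0.5, 0.3), 1.23)
      c2 <- c(0.330, 0.640, 0.560)
      o2 <- place_bonded(cell, c2, c(-0.3, 0.7, 0.65), 1.23)
      mk_c <- function(lab, xyz, ref, U)
        mm_atom(lab, "C", xyz, U = U, Pv = 4.15,
                Plm = c("P10" = 0.24, "P20" = 0.11),
                kappa = 0.99, kappa_prime = 1.04,
                local_axes = list(ref1 = ref), local_symmetry = "cyl")
      mk_o <- function(lab, xyz, ref, U)
        mm_atom(lab, "O", xyz, U = U, Pv = 6.08,
                Plm = c("P10" = -0.11, "P20" = 0.07),
                kappa = 0.985, kappa_prime = 1.02,
                local_axes = list(ref1 = ref), local_symmetry = "cyl")
      atoms <- list(
        mk_c("C1", c1, "O1", c(0.012, 0.014, 0.011, 0.001, 0.002, -0.001)),
        mk_o("O1", o1, "C1", c(0.015, 0.016, 0.014, -0.001, 0.001, 0.002)),
        mk_c("C2", c2, "O2", c(0.013, 0.012, 0.014, -0.002, 0.001, 0.001)),
        mk_o("O2", o2, "C2", c(0.016, 0.014, 0.015, 0.001, -0.002, 0.001)))
      mod <- crystal_model(cell, space_group("P-1"), atoms,
                           ties = list(c("C1", "C2"), c("O1", "O2")))
      attr(mod, "resolution") <- 0.8
      mod
    },
    anharmonic_demo = {
      cell <- unit_cell(5.3, 5.8, 6.2, 90, 99, 90)
      c1 <- c(0.160, 0.210, 0.240)
      o1 <- place_bonded(cell, c1, c(0.75, 0.55, 0.35), 1.23)
      atoms <- list(
        mm_atom("C1", "C", c1, U = c(0.020, 0.024, 0.021, 0.002, 0.003, -0.002),
                Pv = 4.1, Plm = c("P10" = 0.22, "P20" = 0.10),
                kappa = 0.99, kappa_prime = 1.04,
                local_axes = list(ref1 = "O1"), local_symmetry = "cyl",
                C3 = c("C111" = 1.2e-5, "C222" = 8e-6, "C112" = 5e-6),
                use_c3 = TRUE),
        mm_atom("O1", "O", o1, U = c(0.018, 0.019, 0.020, -0.001, 0.002, 0.001),
                Pv = 6.1, Plm = c("P10" = -0.10, "P20" = 0.07),
                kappa = 0.99, kappa_prime = 1.0,
                local_axes = list(ref1 = "C1"), local_symmetry = "cyl"),
        mm_atom("N1", "N", c(0.600, 0.300, 0.700),
                U = c(0.019, 0.021, 0.018, 0.002, -0.001, 0.001),
                Pv = 5.05, Plm = c("P10" = 0.09, "P20" = 0.05),
                kappa = 0.995, kappa_prime = 1.0),
        mm_atom("F1", "F", c(0.520, 0.750, 0.150),
                U = c(0.021, 0.019, 0.022, -0.002, 0.001, 0.002),
                Pv = 7.02, Plm = c("P10" = -0.06),
                kappa = 0.99, kappa_prime = 1.0))
      mod <- crystal_model(cell, space_group("P-1"), atoms)
      attr(mod, "resolution") <- 1.1
      mod
    })
  attr(m, "noise") <- 0.01
  attr(m, "scenario") <- scenario
  m
}

#' Enumerate the unique reflections of a model to a resolution limit
#'
#' Centrosymmetric cells: one representative per Laue group orbit
#' (Friedel-merged). Non-centrosymmetric cells: one representative per
#' rotation orbit, i.e. both Friedel mates are emitted.
#'
#' @param model a [crystal_model()].
#' @param res_limit sin(theta)/lambda limit (1/angstrom).
#' @return integer matrix of h, k, l.
#' @export
unique_reflections <- function(model, res_limit) {
  cell <- model$cell
  hmax <- ceiling(2 * res_limit / sqrt(diag(cell$Gstar)))
  g <- as.matrix(expand.grid(-hmax[1]:hmax[1], -hmax[2]:hmax[2],
                             -hmax[3]:hmax[3]))
  colnames(g) <- NULL
  s <- stol(cell, g)
  g <- g[s <= res_limit & s > 0, , drop = FALSE]
  rots <- if (model$spacegroup$centrosymmetric) laue_rotations(model$spacegroup)
          else point_rotations(model$spacegroup)
  can <- canonical_hkl(g, rots)
  keep <- rowSums(abs(g - can)) == 0
  g[keep, , drop = FALSE]
}

#' Simulate observed intensities from a model
#'
#' Fo^2 = |Fc|^2 (1 + N(0, noise)) with sigma = noise |Fc|^2 + floor
#' (floor = 2% of the median intensity times max(noise, 1e-4)); the
#' simplest noise model consistent with sigma(F^2) data columns.
#' Deterministic under `seed`.
#'
#' @param model ground-truth [crystal_model()].
#' @param res_limit resolution limit (default: the scenario's).
#' @param noise fractional noise level (default: the scenario's, else 1%).
#' @param seed integer seed.
#' @return a [reflection_set()]; attribute `"Fc2_true"` carries the
#'   noise-free intensities.
#' @export
simulate_fobs <- function(model, res_limit = NULL, noise = NULL, seed = 1) {
  if (is.null(res_limit)) res_limit <- attr(model, "resolution") %||% 0.9
  if (is.null(noise)) noise <- attr(model, "noise") %||% 0.01
  stopifnot(noise >= 0)
  hkl <- unique_reflections(model, res_limit)
  Fc2 <- Mod(structure_factor(model, hkl))^2
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  floor_sig <- pmax(noise, 1e-4) * 0.02 * stats::median(Fc2)
  sigma <- noise * Fc2 + floor_sig
  Fo2 <- Fc2 * (1 + stats::rnorm(length(Fc2), 0, noise))
  df <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                   Fo2 = Fo2, sigma = sigma)
  set <- reflection_set(df, model$cell,
                        merged = model$spacegroup$centrosymmetric)
  attr(set, "Fc2_true") <- Fc2
  set
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inject overexposed low-order outliers
#'
#' Deflates the n strongest reflections below `stol_max` (Fo^2 multiplied
#' by `deflation`, sigma unchanged), emulating overexposure: the observed
#' amplitude is far below the model (F_o << F_c). The modified row indices
#' are recorded as ground truth.
#'
#' @param set a [reflection_set()].
#' @param n number of reflections to deflate (>= 1).
#' @param deflation multiplier in (0, 1]; 1 leaves the set unchanged.
#' @param stol_max low-order window (1/angstrom).
#' @return the modified set; attribute `"outlier_rows"` holds the injected
#'   row indices.
#' @export
inject_outliers <- function(set, n = 2, deflation = 0.25, stol_max = 0.5) {
  stopifnot(n >= 1, deflation > 0, deflation <= 1)
  cand <- which(set$data$stol <= stol_max)
  if (length(cand) < n)
    stop("only ", length(cand), " reflections below stol ", stol_max)
  pick <- cand[order(set$data$Fo2[cand], decreasing = TRUE)[seq_len(n)]]
  if (deflation < 1) set$data$Fo2[pick] <- set$data$Fo2[pick] * deflation
  attr(set, "outlier_rows") <- pick
  set
}

#' Assemble a complete scenario (model + simulated data + ground truth)
#'
#' @param scenario scenario name (see [make_toy_crystal()]).
#' @param seed integer seed driving the noise (and outlier bookkeeping).
#' @param ... overrides passed to [simulate_fobs()].
#' @return list with `model`, `reflections`, `truth` (full ground-truth
#'   parameter vector plus scenario extras).
#' @export
make_scenario <- function(scenario, seed = 1, ...) {
  model <- make_toy_crystal(scenario)
  refl <- simulate_fobs(model, seed = seed, ...)
  truth <- list(params = full_params(model))
  if (scenario == "outlier_demo") {
    refl <- inject_outliers(refl)
    truth$outlier_rows <- attr(refl, "outlier_rows")
  }
  list(model = model, reflections = refl, truth = truth,
       scenario = scenario, seed = seed)
}

#' Strip a model to its independent-atom (IAM) starting point
#'
#' Zeroes all deformation populations, resets P_v to the neutral valence
#' count and kappa/kappa' to 1; positions and ADPs are kept. The usual
#' starting point of a multipole refinement strategy.
#'
#' @param model a [crystal_model()].
#' @return the IAM model.
#' @export
iam_model <- function(model) {
  for (i in seq_along(model$atoms)) {
    a <- model$atoms[[i]]
    a$Plm[] <- 0
    a$Pv <- element_entry(a$element)$valence$nel
    a$kappa <- 1; a$kappa_prime <- 1
    model$atoms[[i]] <- a
  }
  model
}

#' Reference refinement strategy of a scenario
#'
#' Stepwise, cumulative parameter release: each step refines the newly
#' added classes jointly with everything already free (one-class-at-a-time
#' refinement stalls on the strongly correlated P_v / kappa pair). The
#' overfit scenario ends with the release of all chemical and
#' local-symmetry constraints; the mirror scenario is a single joint step
#' including the anharmonic coefficients, with a general-position atom
#' pinning the floating origin of the polar directions.
#'
#' @param scenario scenario name (see [make_toy_crystal()]).
#' @param model the scenario's model (for atom labels).
#' @return list of [strategy_step()]s.
#' @export
scenario_strategy <- function(scenario, model) {
  labs <- names(model$atoms)
  switch(scenario,
    overfit_demo = list(
      strategy_step("xyz_U", classes = c("xyz", "U")),
      strategy_step("M_K", classes = c("xyz", "U", "M", "K")),
      strategy_step("D_Q", classes = c("xyz", "U", "M", "D", "Q", "K")),
      strategy_step("KP", classes = c("xyz", "U", "M", "D", "Q", "K", "KP")),
      strategy_step("release", classes = c("xyz", "U", "M", "D", "Q", "K", "KP"),
                    release_ties = TRUE,
                    release_lsym = stats::setNames(rep("none", length(labs)), labs))),
    mirror_special = list(
      strategy_step("joint_C3",
                    classes = c("xyz", "U", "M", "D", "K", "C3"),
                    fix_params = c("O1.x", "O1.z"))),
    outlier_demo = , centro_simple = list(
      strategy_step("joint", classes = c("xyz", "U", "M", "D", "Q", "K"))),
    anharmonic_demo = list(
      strategy_step("joint", classes = c("xyz", "U", "M", "D", "Q", "K")),
      strategy_step("C3", classes = c("xyz", "U", "M", "D", "Q", "K", "C3"))),
    noncentro_pair = list(
      strategy_step("joint", classes = c("xyz", "U", "M", "D", "Q", "K"),
                    fix_params = c("C1.x", "C1.y", "C1.z"))),
    stop("no reference strategy for scenario '", scenario, "'"))
}
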