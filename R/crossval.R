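## k-fold cross-validation of a refinement strategy and the R statistics:
## per-set R_work / R_free, the pooled R_cross ("the R_free for all
## reflections as validation"), <R_work>, and resolution-shell variants.

#' Partition reflections into k cross-validation sets
#'
#' Assigns every reflection to exactly one test set. With
#' `friedel_aware = TRUE` the unit of assignment is the Friedel/Laue group,
#' so a reflection and its mate always share a set (they are not
#' independent observations). Group order is shuffled deterministically
#' under `seed` and groups go greedily to the currently smallest set.
#'
#' @param set a [reflection_set()].
#' @param spacegroup a [space_group()].
#' @param k number of test sets (default 20).
#' @param seed integer seed.
#' @param friedel_aware co-assign Friedel mates (default TRUE).
#' @return object of class `cv_partition`: `k`, `seed`, `assignment`
#'   (integer in 0..k-1 per reflection), `friedel_aware`.
#' @export
make_partition <- function(set, spacegroup, k = 20, seed = 1,
                           friedel_aware = TRUE) {
  n <- n_reflections(set)
  key <- if (friedel_aware)
    friedel_key(as.matrix(set$data[, c("h", "k", "l")]), spacegroup)
  else as.character(seq_len(n))
  groups <- split(seq_len(n), key)
  if (k < 2) stop("k must be at least 2")
  if (k > length(groups))
    stop("k = ", k, " exceeds the number of assignment groups (",
         length(groups), ")")
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  ord <- sample(length(groups))
  sizes <- numeric(k)
  assignment <- integer(n)
  for (gi in ord) {
    tgt <- which.min(sizes)
    assignment[groups[[gi]]] <- tgt - 1L
    sizes[tgt] <- sizes[tgt] + length(groups[[gi]])
  }
  structure(list(k = k, seed = seed, assignment = assignment,
                 friedel_aware = friedel_aware),
            class = "cv_partition")
}

#' Agreement factor R on |F|
#'
#' R = sum | |Fo| - sqrt(s) |Fc| | / sum |Fo| with Fo = sqrt(max(Fo2, 0)).
#' The scale is the work-set scale (F^2 convention, Fo2 ~ s |Fc|^2); it is
#' never re-fitted on a test set.
#'
#' @param Fo2 observed squared structure factors.
#' @param Fc2 model squared structure factors (|Fc|^2, unscaled).
#' @param scale work-set scale factor (> 0).
#' @return R value.
#' @export
r_factor <- function(Fo2, Fc2, scale = 1) {
  if (!length(Fo2)) stop("empty reflection list")
  if (scale <= 0) stop("scale must be positive")
  Fo <- sqrt(pmax(Fo2, 0))
  Fcal <- sqrt(scale * Fc2)
  sum(abs(Fo - Fcal)) / sum(Fo)
}

#' Pooled cross-validation R factor
#'
#' Computes one R factor over the union of all k test-set records, each
#' reflection appearing exactly once; violations of that coverage contract
#' are an error.
#'
#' @param records data.frame with columns `Fo2`, `Fc2`, `scale`, `set` and
#'   a reflection identifier column `refl`.
#' @param n_total expected number of distinct reflections (optional check).
#' @return pooled R value.
#' @export
r_cross <- function(records, n_total = NULL) {
  if (anyDuplicated(records$refl)) {
    dup <- unique(records$refl[duplicated(records$refl)])
    stop("reflections appear in more than one test set: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  if (!is.null(n_total) && nrow(records) != n_total)
    stop("test sets cover ", nrow(records), " of ", n_total, " reflections")
  Fo <- sqrt(pmax(records$Fo2, 0))
  Fcal <- sqrt(records$scale * records$Fc2)
  sum(abs(Fo - Fcal)) / sum(Fo)
}

#' Approximate standard deviation of R_free
#'
#' sigma(R_free) ~ R_free / sqrt(2 n), with n the number of reflections in
#' the test set.
#'
#' @param r_free the R_free value.
#' @param n test-set size (>= 1).
#' @return approximate standard deviation.
#' @export
sigma_rfree <- function(r_free, n) {
  stopifnot(n >= 1)
  r_free / sqrt(2 * n)
}

#' Run k-fold cross-validation of a refinement strategy
#'
#' For every training set (all data minus one test set) and for the total
#' data set: shake the starting model, run the staged refinement, and for
#' every step perform a zero-cycle structure-factor calculation on the
#' member's test set. Test reflections are never used for refinement; the
#' test-set scale is the training scale. Per step the result pools the
#' zero-cycle records of all k test sets into R_cross and keeps per-set
#' R_work/R_free, shell-resolved values at `cut`, and the free-parameter
#' vectors of all members for the distribution diagnostics.
#'
#' @param data a [reflection_set()] covering all reflections.
#' @param model starting [crystal_model()].
#' @param strategy list of [strategy_step()]s.
#' @param partition a [make_partition()] result for `data`.
#' @param shake_amplitude coordinate shake (fractional); 0 disables.
#' @param seed base seed; member i shakes with seed + i, the all-data
#'   refinement with seed (independent of the partition).
#' @param cut resolution-shell split (1/angstrom).
#' @param keep_models keep every member model per step (needed for density
#'   error cubes and BCP distributions).
#' @return object of class `cv_run`.
#' @export
run_cv <- function(data, model, strategy, partition,
                   shake_amplitude = 0.002, seed = 1, cut = 0.5,
                   keep_models = FALSE) {
  k <- partition$k
  n <- n_reflections(data)
  if (length(partition$assignment) != n)
    stop("partition does not match the reflection set")
  if (!setequal(unique(partition$assignment), 0:(k - 1)))
    stop("partition sets are not 0..k-1 (disjoint, exhaustive)")
  hkl_all <- as.matrix(data$data[, c("h", "k", "l")])
  geom_all <- sf_geometry(model$cell, model$spacegroup, hkl_all)

  run_member <- function(train_idx, shake_seed) {
    m0 <- if (shake_amplitude > 0) shake(model, shake_amplitude, shake_seed)
          else model
    fits <- staged_refinement(m0, subset_refl(data, train_idx), strategy)
    ## zero-cycle F over all reflections per step (work R comes from the
    ## fit; test records are read off the complement)
    Fc2_all <- lapply(fits, function(f)
      Mod(structure_factor(f$model, hkl_all, geom_all))^2)
    list(fits = fits, Fc2 = Fc2_all)
  }

  members <- vector("list", k)
  for (i in seq_len(k)) {
    train <- partition$assignment != (i - 1)
    members[[i]] <- run_member(train, seed + i)
  }
  total <- run_member(rep(TRUE, n), seed)

  stol_v <- data$data$stol
  Fo2 <- data$data$Fo2
  steps <- vector("list", length(strategy))
  names(steps) <- vapply(strategy, `[[`, character(1), "name")
  for (si in seq_along(strategy)) {
    recs <- vector("list", k)
    r_work <- r_free <- numeric(k)
    r_work_lo <- r_work_hi <- numeric(k)
    for (i in seq_len(k)) {
      test <- partition$assignment == (i - 1)
      fit <- members[[i]]$fits[[si]]
      Fc2 <- members[[i]]$Fc2[[si]]
      r_work[i] <- r_factor(Fo2[!test], Fc2[!test], fit$scale)
      r_free[i] <- r_factor(Fo2[test], Fc2[test], fit$scale)
      lo <- !test & stol_v <= cut
      hi <- !test & stol_v > cut
      r_work_lo[i] <- if (any(lo)) r_factor(Fo2[lo], Fc2[lo], fit$scale) else NA
      r_work_hi[i] <- if (any(hi)) r_factor(Fo2[hi], Fc2[hi], fit$scale) else NA
      recs[[i]] <- data.frame(refl = which(test), set = i - 1L,
                              Fo2 = Fo2[test], Fc2 = Fc2[test],
                              sigma = data$data$sigma[test],
                              stol = stol_v[test], scale = fit$scale)
    }
    records <- do.call(rbind, recs)
    lo <- records$stol <= cut
    fit_t <- total$fits[[si]]
    Fc2_t <- total$Fc2[[si]]
    V <- do.call(rbind, lapply(members, function(m) m$fits[[si]]$free))
    steps[[si]] <- list(
      name = strategy[[si]]$name,
      r_work = r_work, r_free = r_free,
      r_work_mean = mean(r_work),
      r_work_mean_low = mean(r_work_lo), r_work_mean_high = mean(r_work_hi),
      r_cross = r_cross(records, n),
      r_cross_low = if (any(lo)) r_cross(records[lo, ], sum(lo)) else NA,
      r_cross_high = if (any(!lo)) r_cross(records[!lo, ], sum(!lo)) else NA,
      r_all = r_factor(Fo2, Fc2_t, fit_t$scale),
      records = records,
      free_members = V,
      free_total = fit_t$free,
      su_total = fit_t$su,
      selected = fit_t$selected,
      converged = vapply(members, function(m) m$fits[[si]]$converged, logical(1)),
      models = if (keep_models)
        lapply(members, function(m) m$fits[[si]]$model),
      model_total = if (keep_models) fit_t$model)
  }
  structure(list(steps = steps, partition = partition, cut = cut,
                 k = k, seed = seed,
                 n_reflections = n),
            class = "cv_run")
}

#' @export
print.cv_run <- function(x, ...) {
  cat(sprintf("cross-validation run: k = %d, %d reflections, %d step(s)\n",
              x$k, x$n_reflections, length(x$steps)))
  for (s in x$steps)
    cat(sprintf("  %-24s <R_work>=%.4f R_cross=%.4f R_all=%.4f\n",
                s$name, s$r_work_mean, s$r_cross, s$r_all))
  invisible(x)
}

#' Per-step Delta-R table
#'
#' Differences of <R_work> and R_cross between consecutive strategy steps,
#' overall and in the low/high resolution shells, with the overfit flag
#' (Delta R_cross > 0 while Delta <R_work> < 0: the work residual drops
#' because added parameters fit noise, while the validation residual
#' rises).
#'
#' @param cv a [run_cv()] result with at least two steps.
#' @return data.frame, one row per step transition.
#' @export
delta_r_table <- function(cv) {
  if (length(cv$steps) < 2) stop("need at least two steps")
  out <- list()
  for (i in 2:length(cv$steps)) {
    a <- cv$steps[[i - 1]]; b <- cv$steps[[i]]
    out[[i - 1]] <- data.frame(
      step = b$name, from = a$name,
      d_r_work = b$r_work_mean - a$r_work_mean,
      d_r_cross = b$r_cross - a$r_cross,
      d_r_work_low = b$r_work_mean_low - a$r_work_mean_low,
      d_r_cross_low = b$r_cross_low - a$r_cross_low,
      d_r_work_high = b$r_work_mean_high - a$r_work_mean_high,
      d_r_cross_high = b$r_cross_high - a$r_cross_high,
      overfit = (b$r_cross - a$r_cross) > 0 &
        (b$r_work_mean - a$r_work_mean) < 0)
  }
  do.call(rbind, out)
}

#' Write the per-step R statistics of a CV run as CSV
#'
#' @param cv a [run_cv()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cv_report <- function(cv, path) {
  rows <- lapply(cv$steps, function(s) data.frame(
    step = s$name, r_work_mean = s$r_work_mean, r_cross = s$r_cross,
    r_all = s$r_all,
    r_work_mean_low = s$r_work_mean_low, r_cross_low = s$r_cross_low,
    r_work_mean_high = s$r_work_mean_high, r_cross_high = s$r_cross_high,
    r_free_min = min(s$r_free), r_free_max = max(s$r_free),
    n_converged = sum(s$converged)))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
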