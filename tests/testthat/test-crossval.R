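test_that("partitions are disjoint, exhaustive, balanced and Friedel-aware", {
  sc <- make_scenario("noncentro_pair", seed = 1)
  refl <- sc$reflections
  sg <- sc$model$spacegroup
  part <- make_partition(refl, sg, k = 20, seed = 3)
  expect_equal(part$k, 20)                      # the k = 20 default regime
  a <- part$assignment
  expect_length(a, n_reflections(refl))
  expect_setequal(unique(a), 0:19)
  ## Friedel mates share a set
  key <- friedel_key(as.matrix(refl$data[, c("h", "k", "l")]), sg)
  expect_true(all(tapply(a, key, function(x) length(unique(x))) == 1))
  ## near-equal sizes (within one pairing unit = 2 reflections)
  expect_lte(diff(range(table(a))), 2)
  ## deterministic under seed
  expect_identical(make_partition(refl, sg, k = 20, seed = 3)$assignment, a)
  expect_false(identical(make_partition(refl, sg, k = 20, seed = 4)$assignment, a))
  ## k = 1 and k > group count are rejected
  expect_error(make_partition(refl, sg, k = 1), "at least 2")
  expect_error(make_partition(refl, sg, k = 1e6), "exceeds")
})

test_that("100 unpaired reflections at k = 20 give five per test set", {
  df <- data.frame(h = 1:100, k = 0L, l = 0L, Fo2 = 1, sigma = 1)
  rs <- reflection_set(df, unit_cell(300, 10, 10))
  part <- make_partition(rs, space_group("P1"), k = 20, seed = 1,
                         friedel_aware = FALSE)
  expect_true(all(table(part$assignment) == 5))
})

test_that("r_factor matches hand arithmetic and an independent recomputation", {
  expect_equal(r_factor(c(100, 25), c(100, 25), 1), 0)
  ## Fo = (10, 10), Fc = (9, 11): R = (1 + 1)/20 = 0.10
  expect_equal(r_factor(c(100, 100), c(81, 121), 1), 0.1)
  expect_error(r_factor(numeric(0), numeric(0)), "empty")
  expect_error(r_factor(1, 1, scale = 0), "positive")
  set.seed(8)
  Fo2 <- runif(200, 1, 400); Fc2 <- Fo2 * (1 + rnorm(200, 0, 0.1))
  s <- 1.7
  oracle <- sum(abs(sqrt(Fo2) - sqrt(s * Fc2))) / sum(sqrt(Fo2))
  expect_equal(r_factor(Fo2, Fc2, s), oracle)
  ## negative Fo2 truncated at zero on the |F| scale
  expect_equal(r_factor(c(-4, 100), c(4, 100), 1),
               (2 + 0) / (0 + 10))
})

test_that("r_cross pools test sets and enforces single coverage", {
  ## two hand-built sets
  rec <- data.frame(refl = 1:4, set = c(0, 0, 1, 1),
                    Fo2 = c(100, 64, 25, 81), Fc2 = c(81, 64, 36, 64),
                    scale = 1)
  want <- (abs(10 - 9) + 0 + abs(5 - 6) + abs(9 - 8)) / (10 + 8 + 5 + 9)
  expect_equal(r_cross(rec), want)
  ## pooled value lies between the per-set values
  r0 <- r_factor(rec$Fo2[1:2], rec$Fc2[1:2])
  r1 <- r_factor(rec$Fo2[3:4], rec$Fc2[3:4])
  expect_gte(r_cross(rec), min(r0, r1))
  expect_lte(r_cross(rec), max(r0, r1))
  ## k identical per-set R and sum(Fo): pooled equals the common value
  rec2 <- data.frame(refl = 1:4, set = c(0, 0, 1, 1),
                     Fo2 = c(100, 4, 100, 4), Fc2 = c(121, 1, 121, 1),
                     scale = 1)
  expect_equal(r_cross(rec2), r_factor(c(100, 4), c(121, 1)))
  ## duplicated reflection -> coverage error
  bad <- rec; bad$refl[3] <- 1
  expect_error(r_cross(bad), "more than one test set")
  expect_error(r_cross(rec, n_total = 99), "cover")
})

test_that("sigma_rfree evaluates R/sqrt(2n)", {
  expect_equal(sigma_rfree(0.02, 200), 0.001)
  expect_equal(sigma_rfree(0.02, 2e8), 0.001 / 1000)
  expect_error(sigma_rfree(0.02, 0))
})

test_that("a small CV run satisfies the coverage and no-overfit contracts", {
  sc <- make_scenario("centro_simple", seed = 6)
  part <- make_partition(sc$reflections, sc$model$spacegroup, k = 5, seed = 6)
  strat <- scenario_strategy("centro_simple", sc$model)
  cv <- run_cv(sc$reflections, sc$model, strat, part, seed = 11)
  st <- cv$steps[[1]]
  ## every reflection appears exactly once across the k test records
  expect_setequal(st$records$refl, seq_len(n_reflections(sc$reflections)))
  expect_false(anyDuplicated(st$records$refl) > 0)
  ## starting from the generating model, R_cross tracks <R_work> within
  ## noise (no overfitting present)
  expect_lt(abs(st$r_cross - st$r_work_mean), 0.003)
  expect_true(all(st$r_work > 0), TRUE)
  ## shells: counts agree with split_by_resolution
  sp <- split_by_resolution(sc$reflections, cv$cut)
  expect_equal(sum(st$records$stol <= cv$cut), n_reflections(sp$low))
})

test_that("the all-data refinement is blind to the partition labels", {
  sc <- make_scenario("centro_simple", seed = 2)
  strat <- list(strategy_step("joint", c("xyz", "U", "M", "K")))
  p1 <- make_partition(sc$reflections, sc$model$spacegroup, k = 4, seed = 1)
  p2 <- make_partition(sc$reflections, sc$model$spacegroup, k = 4, seed = 99)
  cv1 <- run_cv(sc$reflections, sc$model, strat, p1, seed = 5)
  cv2 <- run_cv(sc$reflections, sc$model, strat, p2, seed = 5)
  expect_identical(cv1$steps[[1]]$free_total, cv2$steps[[1]]$free_total)
  expect_identical(cv1$steps[[1]]$r_all, cv2$steps[[1]]$r_all)
})

test_that("delta_r_table differences, flags and degenerate cases", {
  fake_step <- function(name, rw, rc, rwl = rw, rcl = rc, rwh = rw, rch = rc)
    list(name = name, r_work_mean = rw, r_cross = rc,
         r_work_mean_low = rwl, r_cross_low = rcl,
         r_work_mean_high = rwh, r_cross_high = rch)
  cv <- structure(list(steps = list(fake_step("a", 0.03, 0.032),
                                    fake_step("b", 0.03, 0.032),
                                    fake_step("c", 0.028, 0.034)),
                       cut = 0.5), class = "cv_run")
  dt <- delta_r_table(cv)
  expect_equal(dt$d_r_work, c(0, -0.002))
  expect_equal(dt$d_r_cross, c(0, 0.002))
  expect_identical(dt$overfit, c(FALSE, TRUE))
  expect_error(delta_r_table(structure(list(steps = cv$steps[1]),
                                       class = "cv_run")),
               "two steps")
})
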