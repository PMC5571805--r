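## Parameter-distribution diagnostics across the k refinements, the
## Shapiro-Wilk normality screen, the Cochran expectation correction, the
## five outlier tables, per-set R_free outliers, the strong-low-order
## reflection scan and Kuhs' resolution rule.

#' Cochran correction factor E[s]/sigma
#'
#' Expected ratio of the sample standard deviation of k independent normal
#' draws to the population value, from Cochran's theorem on the chi
#' distribution: sqrt(2/(k-1)) Gamma(k/2) / Gamma((k-1)/2). Strictly
#' increasing in k with limit 1; e.g. 0.973 for ten test sets, 0.987 for
#' 20 and 0.995 for 50. If all k refinements were independent, s_mean of a
#' parameter distribution would equal this factor times s_total.
#'
#' @param k number of test sets (>= 2).
#' @return the correction factor.
#' @examples
#' round(cochran_factor(10), 3)  # 0.973
#' @export
cochran_factor <- function(k) {
  if (any(k < 2)) stop("k must be at least 2")
  sqrt(2 / (k - 1)) * exp(lgamma(k / 2) - lgamma((k - 1) / 2))
}

#' Shapiro-Wilk normality test
#'
#' W and p for a small sample; a thin wrapper over the standard
#' implementation ([stats::shapiro.test()]), kept as the package-level
#' surface so the flag rule (W < 0.905 or p < 0.05) lives next to it.
#'
#' @param values numeric sample, 3 <= n <= 5000, not all equal.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  if (length(values) < 3 || length(values) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (max(values) == min(values)) stop("constant sample")
  st <- stats::shapiro.test(values)
  list(W = unname(st$statistic), p = st$p.value)
}

#' Shapiro-Wilk flag rule
#'
#' TRUE when the normality hypothesis is refused: W below `w_crit`
#' (default 0.905) or p below `alpha` (default 0.05).
#' @param W,p test results.
#' @param w_crit,alpha thresholds.
#' @return logical.
#' @export
sw_flagged <- function(W, p, w_crit = 0.905, alpha = 0.05) {
  W < w_crit | p < alpha
}

#' Parameter-distribution report across k refinements
#'
#' Compares the free parameters of the k cross-validation fits with the
#' all-data fit and emits the five diagnostic tables:
#' \enumerate{
#'   \item all (parameter, set) with |v_total - v_i| > 3 s_total;
#'   \item parameters failing the Shapiro-Wilk screen (W < 0.905 or
#'     p < 0.05);
#'   \item parameters with |v_total - v_mean| / s_total > 0.5;
#'   \item parameters with s_mean > s_total (a sign of problems: the
#'     expected s_mean is below s_total because the refinements share
#'     data);
#'   \item outlier count (from table 1) per test set.
#' }
#'
#' @param fits list of k `fit_result`s with identical free-parameter
#'   structure (e.g. one step of [run_cv()]), or a `cv_run`.
#' @param total_fit the all-data `fit_result` (ignored when `fits` is a
#'   `cv_run`).
#' @param step step name or index when `fits` is a `cv_run` (default:
#'   last step).
#' @return object of class `diagnostics_report`: `parameters` (per-param
#'   summary), `tables` (the five tables), `k`.
#' @export
parameter_report <- function(fits, total_fit = NULL, step = NULL) {
  if (inherits(fits, "cv_run")) {
    st <- if (is.null(step)) fits$steps[[length(fits$steps)]]
          else fits$steps[[step]]
    V <- st$free_members[, st$selected, drop = FALSE]
    v_total <- st$free_total[st$selected]
    s_total <- st$su_total
  } else {
    if (is.null(total_fit)) stop("total_fit required")
    sel <- total_fit$selected
    for (f in fits)
      if (!identical(names(f$free), names(total_fit$free)))
        stop("free-parameter structure differs between fits: ",
             paste(utils::head(setdiff(names(total_fit$free), names(f$free))),
                   collapse = ", "))
    V <- do.call(rbind, lapply(fits, function(f) f$free[sel]))
    v_total <- total_fit$free[sel]
    s_total <- total_fit$su
  }
  k <- nrow(V)
  pnames <- colnames(V)
  v_mean <- colMeans(V)
  s_mean <- apply(V, 2, stats::sd)
  sw <- lapply(seq_along(pnames), function(j) {
    vi <- V[, j]
    if (max(vi) == min(vi)) list(W = NA_real_, p = NA_real_)
    else shapiro_wilk(vi)
  })
  W <- vapply(sw, `[[`, numeric(1), "W")
  p <- vapply(sw, `[[`, numeric(1), "p")
  params <- data.frame(parameter = pnames, v_total = unname(v_total),
                       s_total = unname(s_total), v_mean = unname(v_mean),
                       s_mean = unname(s_mean), W = W, p = p,
                       row.names = NULL)

  dev <- abs(sweep(V, 2, v_total)) / rep(pmax(s_total, .Machine$double.eps),
                                         each = k)
  hit <- which(dev > 3, arr.ind = TRUE)
  t1 <- if (nrow(hit)) data.frame(parameter = pnames[hit[, 2]],
                                  set = hit[, 1] - 1L,
                                  v_i = V[hit], v_total = unname(v_total[hit[, 2]]),
                                  dev_over_s = dev[hit], row.names = NULL)
        else data.frame(parameter = character(0), set = integer(0),
                        v_i = numeric(0), v_total = numeric(0),
                        dev_over_s = numeric(0))
  swf <- !is.na(W) & sw_flagged(W, p)
  t2 <- params[swf, c("parameter", "W", "p")]
  ratio3 <- abs(v_mean - v_total) / pmax(s_total, .Machine$double.eps)
  t3 <- data.frame(parameter = pnames, ratio = unname(ratio3),
                   row.names = NULL)[ratio3 > 0.5, ]
  t4 <- params[s_mean > s_total & !is.na(s_total),
               c("parameter", "s_mean", "s_total")]
  counts <- integer(k)
  if (nrow(t1)) {
    tb <- table(factor(t1$set, levels = 0:(k - 1)))
    counts <- as.integer(tb)
  }
  t5 <- data.frame(set = 0:(k - 1), outliers = counts)
  out <- structure(list(parameters = params,
                        tables = list(deviation = t1, shapiro_wilk = t2,
                                      mean_shift = t3, s_mean_excess = t4,
                                      per_set = t5),
                        k = k),
                   class = "diagnostics_report")
  attr(out, "members") <- stats::setNames(lapply(seq_along(pnames),
                                                 function(j) V[, j]), pnames)
  out
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf("parameter-distribution report (k = %d, %d parameters)\n",
              x$k, nrow(x$parameters)))
  cat(sprintf("  table 1 |v_total-v_i|>3s_total : %d entries\n",
              nrow(x$tables$deviation)))
  cat(sprintf("  table 2 Shapiro-Wilk flags     : %d parameters\n",
              nrow(x$tables$shapiro_wilk)))
  cat(sprintf("  table 3 |v_total-v_mean|>0.5s  : %d parameters\n",
              nrow(x$tables$mean_shift)))
  cat(sprintf("  table 4 s_mean > s_total       : %d parameters\n",
              nrow(x$tables$s_mean_excess)))
  invisible(x)
}

#' Scan per-set R_free values for outlying test sets
#'
#' Flags sets whose R_free exceeds median + `m` sigma. The reference sigma
#' is the larger of the counting-statistics approximation
#' R_free/sqrt(2n) (evaluated at the median) and the robust spread of the
#' per-set values (1.4826 MAD). The counting formula alone understates the
#' real set-to-set variation because the k refined models differ; the MAD
#' floor keeps the false-flag rate low while leaving genuine outliers
#' (tens of sigma above the median) flagged.
#'
#' @param r_free numeric vector of per-set R_free values (k >= 3).
#' @param n_per_set reflections per test set (scalar).
#' @param m flag threshold in sigma units (default 3).
#' @return integer vector of flagged set indices (0-based, matching cv_set).
#' @export
rfree_set_scan <- function(r_free, n_per_set, m = 3) {
  if (length(r_free) < 3) stop("need at least 3 sets")
  med <- stats::median(r_free)
  sig <- max(sigma_rfree(med, n_per_set), stats::mad(r_free))
  which(r_free > med + m * sig) - 1L
}

#' Scan zero-cycle records for suspect strong low-order reflections
#'
#' Flags reflections that are simultaneously low-order (stol below
#' `stol_max`), strong (scaled model intensity in the top `1 - strong_q`
#' fraction) and badly under-observed ((s Fc^2 - Fo^2)/sigma above
#' `z_min`) - the F_o << F_c signature of an overexposed reflection. Also
#' returns shell means of Fo^2/(s Fc^2), the DRK-style table.
#'
#' @param records data.frame with `Fo2`, `Fc2`, `sigma`, `stol` and a
#'   `scale` column (or use `scale`).
#' @param scale overall scale if not a column.
#' @param stol_max low-order cut (1/angstrom).
#' @param strong_q intensity quantile defining "strong" (default 0.9: top
#'   decile).
#' @param z_min deviation threshold in sigma (default 10).
#' @param shells number of resolution shells for the ratio table.
#' @return list: `flagged` (row indices into `records`), `table` (the
#'   flagged rows with z-scores), `shell_ratio` (per-shell mean
#'   Fo^2/(s Fc^2)).
#' @export
reflection_outlier_scan <- function(records, scale = NULL, stol_max = 0.5,
                                    strong_q = 0.9, z_min = 10,
                                    shells = 10) {
  s <- if (!is.null(records$scale)) records$scale
       else if (!is.null(scale)) scale else 1
  Ical <- s * records$Fc2
  z <- (Ical - records$Fo2) / records$sigma
  strong <- Ical >= stats::quantile(Ical, strong_q)
  flag <- which(records$stol <= stol_max & strong & z >= z_min)
  brk <- seq(0, max(records$stol) + 1e-9, length.out = shells + 1)
  shell <- cut(records$stol, brk, include.lowest = TRUE)
  ratio <- tapply(records$Fo2 / Ical, shell, mean)
  tab <- records[flag, , drop = FALSE]
  tab$z <- z[flag]
  list(flagged = flag, table = tab,
       shell_ratio = data.frame(shell = names(ratio),
                                mean_Fo2_over_Fc2 = as.numeric(ratio)))
}

#' Kuhs' minimum-resolution rule for anharmonic refinement
#'
#' Q_n = 2 sqrt(n) (2 pi)^(-1/2) (2 ln 2)^(1/2) <u^2>^(-1/2), the minimum
#' data resolution (on the q = 4 pi sin(theta)/lambda scale) for a
#' meaningful refinement of order-n anharmonic displacement terms.
#'
#' @param u2_mean mean-square displacement <u^2> (A^2, > 0).
#' @param n anharmonic order (2, 3 or 4; third-order Gram-Charlier: 3).
#' @return Q_n in 1/angstrom.
#' @export
kuhs_q <- function(u2_mean, n = 3) {
  if (any(u2_mean <= 0)) stop("<u^2> must be positive")
  if (!all(n %in% 2:4)) stop("order n must be 2, 3 or 4")
  2 * sqrt(n) * (2 * pi)^(-0.5) * sqrt(2 * log(2)) / sqrt(u2_mean)
}

#' Is Kuhs' rule satisfied at a given data resolution?
#'
#' @param u2_mean mean-square displacement (A^2).
#' @param stol_max data resolution as max sin(theta)/lambda (1/angstrom);
#'   compared with Q_n on the q = 4 pi stol scale.
#' @param n anharmonic order.
#' @return logical.
#' @export
kuhs_satisfied <- function(u2_mean, stol_max, n = 3) {
  4 * pi * stol_max >= kuhs_q(u2_mean, n)
}
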