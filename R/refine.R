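## Constrained nonlinear least-squares refinement on F^2.
##
## Minimizes sum w (Fo^2 - s |Fc|^2)^2, w = 1/sigma^2(Fo^2), over a
## selected set of free parameters plus one overall scale s, by
## Gauss-Newton with Levenberg damping. Standard uncertainties come from
## the inverse normal matrix scaled by the goodness of fit. Jacobian
## columns are forward differences recomputed only for the atoms a free
## parameter drives (exact for the parameters F is linear in).

#' Define a refinement strategy step
#'
#' @param name step label.
#' @param classes parameter classes to refine: subset of `xyz, U, C3, M, D,
#'   Q, O, H, K, KP` (Fig.-2-style abbreviations: M monopoles, D dipoles,
#'   Q quadrupoles, O octupoles, H hexadecapoles, U displacement, K kappa,
#'   KP kappa').
#' @param atoms restrict the selection to these atom labels (NULL = all).
#' @param filter data filter: `"all"`, `"low"` (stol <= cut) or `"high"`
#'   (stol >= cut).
#' @param cut resolution cut for the filter (1/angstrom); defaults to 0.5
#'   for `"low"` and 0.8 for `"high"`.
#' @param release_lsym named character vector `label = code` lowering
#'   local-symmetry constraints before this step.
#' @param release_ties drop all chemical ties before this step.
#' @param add_c3 atom labels switched to anharmonic (third-order
#'   Gram-Charlier) treatment in this step.
#' @param fix_params free-parameter names excluded from refinement in this
#'   step (e.g. one atom's coordinates along polar directions, pinning a
#'   floating origin).
#' @param max_cycles,tol convergence control: stop when max |shift/esd| <
#'   `tol` or after `max_cycles` cycles.
#' @return object of class `strategy_step`.
#' @export
strategy_step <- function(name, classes, atoms = NULL, filter = "all",
                          cut = NULL, release_lsym = NULL,
                          release_ties = FALSE, add_c3 = NULL,
                          fix_params = NULL, max_cycles = 50, tol = 0.01) {
  if (!length(classes)) stop("step '", name, "': parameter selection is empty")
  if (!filter %in% c("all", "low", "high"))
    stop("filter must be all, low or high")
  if (is.null(cut)) cut <- if (filter == "high") 0.8 else 0.5
  structure(list(name = name, classes = classes, atoms = atoms,
                 filter = filter, cut = cut, release_lsym = release_lsym,
                 release_ties = release_ties, add_c3 = add_c3,
                 fix_params = fix_params, max_cycles = max_cycles, tol = tol),
            class = "strategy_step")
}

## constraint edits of a step, applied to the model before refinement
apply_step_edits <- function(model, step) {
  if (!is.null(step$release_lsym)) {
    for (lab in names(step$release_lsym)) {
      if (is.null(model$atoms[[lab]])) stop("release_lsym: unknown atom ", lab)
      model$atoms[[lab]]$local_symmetry <- step$release_lsym[[lab]]
    }
  }
  if (isTRUE(step$release_ties)) model$ties <- list()
  for (lab in step$add_c3) {
    if (is.null(model$atoms[[lab]])) stop("add_c3: unknown atom ", lab)
    model$atoms[[lab]]$use_c3 <- TRUE
  }
  model
}

filter_reflections <- function(set, filter, cut) {
  switch(filter,
         all = set,
         low = subset_refl(set, set$data$stol <= cut),
         high = subset_refl(set, set$data$stol >= cut))
}

## forward-difference step per parameter class
fd_step <- function(class) {
  switch(class, xyz = 1e-5, U = 1e-6, C3 = 1e-6, K = 1e-4, KP = 1e-4, 1e-4)
}

#' Randomly shake a model
#'
#' Applies random shifts to all coordinates and U_ij values before a
#' cross-validation refinement so the validation sets are unbiased:
#' coordinates are perturbed by N(0, amplitude) (fractional), diagonal U
#' multiplicatively by N(0, u_frac), off-diagonal U additively on the scale
#' of the mean diagonal. Constraints are re-applied afterwards, so
#' special-position and tie relations survive the shake.
#'
#' @param model a [crystal_model()].
#' @param amplitude coordinate shake s.d. (fractional units).
#' @param seed integer seed (deterministic perturbation).
#' @param u_frac relative shake of the displacement parameters.
#' @param cmap constraint map to re-apply (default: the model's full map).
#' @return perturbed model.
#' @export
shake <- function(model, amplitude = 0.002, seed = 1, u_frac = 0.05,
                  cmap = NULL) {
  ## the constraint map must come from the unshaken model: the shaken
  ## coordinates no longer sit exactly on their special positions
  if (is.null(cmap)) cmap <- constraint_map(model)
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  for (i in seq_along(model$atoms)) {
    a <- model$atoms[[i]]
    a$xyz <- a$xyz + stats::rnorm(3, 0, amplitude)
    umean <- mean(abs(a$U[1:3]))
    a$U[1:3] <- a$U[1:3] * (1 + stats::rnorm(3, 0, u_frac))
    a$U[4:6] <- a$U[4:6] + stats::rnorm(3, 0, u_frac * umean / 3)
    model$atoms[[i]] <- a
  }
  apply_constraints(model, cmap)
}

## save/restore the global RNG so seeded helpers do not disturb callers
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Least-squares refinement of one strategy step
#'
#' @param model a [crystal_model()]; the step's constraint edits are
#'   applied first.
#' @param work_set a [reflection_set()] (training data).
#' @param step a [strategy_step()].
#' @param scale fixed overall scale (Fo^2 = scale * |Fc|^2); NULL refines
#'   it alongside the model parameters.
#' @return object of class `fit_result`: refined `model`, `scale`, free
#'   vector `free` (all free parameters), `selected` names, `su` (standard
#'   uncertainties of the selected parameters), R statistics (`r_f`,
#'   `r_f2`, `gof`), `cycles`, `converged`, `condition`.
#' @export
lsq_refine <- function(model, work_set, step, scale = NULL) {
  model <- apply_step_edits(model, step)
  cmap <- constraint_map(model)
  model <- apply_constraints(model, cmap)
  sel <- resolve_selection(cmap, step$classes, step$atoms)
  ## C3 columns only for atoms flagged anharmonic
  if ("C3" %in% step$classes) {
    c3cols <- which(cmap$free_class == "C3")
    anh <- names(Filter(function(a) isTRUE(a$use_c3), model$atoms))
    drop <- c3cols[!vapply(cmap$free_atoms[c3cols],
                           function(a) any(a %in% anh), logical(1))]
    sel <- setdiff(sel, drop)
  } else sel <- setdiff(sel, which(cmap$free_class == "C3"))
  if (!is.null(step$fix_params))
    sel <- setdiff(sel, which(cmap$free_names %in% step$fix_params))
  if (!length(sel)) stop("step '", step$name, "': no refinable parameters selected")
  dat <- filter_reflections(work_set, step$filter, step$cut)
  n <- n_reflections(dat)
  npar <- length(sel) + is.null(scale)
  if (npar >= n)
    stop("step '", step$name, "': ", npar, " parameters but only ", n,
         " reflections in the filtered work set")
  hkl <- as.matrix(dat$data[, c("h", "k", "l")])
  Fo2 <- dat$data$Fo2
  w <- 1 / dat$data$sigma^2
  sw <- sqrt(w)
  geom <- sf_geometry(model$cell, model$spacegroup, hkl)
  fit_scale <- is.null(scale)

  fvec <- pack_parameters(model, cmap)
  selnames <- cmap$free_names[sel]
  contrib <- sf_atom_contributions(model, geom)
  Fc <- rowSums(contrib)
  Fc2 <- Mod(Fc)^2
  if (fit_scale) scale <- sum(w * Fo2 * Fc2) / sum(w * Fc2^2)
  resid <- sw * (Fo2 - scale * Fc2)
  sse <- sum(resid^2)

  ## rows of the full parameter vector feeding each selected column;
  ## kappa/kappa' columns fall back to per-atom finite differences
  kap_cols <- which(cmap$free_class[sel] %in% c("K", "KP"))
  ana_rows <- character(0)
  col_rows <- vector("list", length(sel))
  for (jj in seq_along(sel)) {
    if (jj %in% kap_cols) next
    rows <- which(cmap$A[, sel[jj]] != 0)
    col_rows[[jj]] <- rows
    ana_rows <- union(ana_rows, cmap$full_names[rows])
  }

  lambda <- 1e-3
  cycles <- 0; converged <- FALSE
  su <- rep(NA_real_, length(sel)); cond <- NA_real_
  for (cyc in seq_len(step$max_cycles)) {
    cycles <- cyc
    ## Jacobian of residuals wrt (selected free params, scale):
    ## analytic dF/dp for everything except kappa/kappa'
    de <- sf_model_derivs(model, geom, ana_rows)
    contrib <- de$contrib; Fc <- de$F; Fc2 <- Mod(Fc)^2
    J <- matrix(0, n, npar)
    for (jj in seq_along(sel)) {
      j <- sel[jj]
      if (jj %in% kap_cols) {
        dj <- fd_step(cmap$free_class[j])
        f2 <- fvec; f2[j] <- f2[j] + dj
        m2 <- unpack_parameters(f2, model, cmap)
        aff <- cmap$free_atoms[[j]]
        dcol <- (rowSums(sf_atom_contributions(m2, geom, aff)) -
                 rowSums(contrib[, aff, drop = FALSE])) / dj
      } else {
        rows <- col_rows[[jj]]
        dcol <- de$derivs[, cmap$full_names[rows], drop = FALSE] %*%
          cmap$A[rows, j]
      }
      dFc2 <- 2 * Re(Conj(Fc) * dcol)
      J[, jj] <- -scale * sw * dFc2
    }
    if (fit_scale) J[, npar] <- -sw * Fc2
    ## exact rank check: a genuinely null/collinear direction is an error
    sv <- svd(J, nu = 0, nv = min(n, npar))
    cond <- sv$d[1] / max(sv$d[length(sv$d)], .Machine$double.xmin)
    null_idx <- which(sv$d < sv$d[1] * 1e-10)
    if (length(null_idx)) {
      culprit <- unique(unlist(lapply(null_idx, function(ni) {
        v <- abs(sv$v[, ni])
        c(selnames, if (fit_scale) "scale")[v > 0.3]
      })))
      stop("singular normal matrix in step '", step$name,
           "'; null-space parameters: ", paste(culprit, collapse = ", "))
    }
    JtJ <- crossprod(J)
    g <- crossprod(J, resid)
    improved <- FALSE
    for (try in 1:12) {
      Aug <- JtJ + lambda * diag(diag(JtJ), npar)
      delta <- tryCatch(solve(Aug, -g), error = function(e) NULL)
      if (!is.null(delta)) {
        f2 <- fvec; f2[sel] <- f2[sel] + delta[seq_along(sel)]
        s2 <- if (fit_scale) scale + delta[npar] else scale
        ## guard the positivity of kappa and scale
        kidx <- sel[cmap$free_class[sel] %in% c("K", "KP")]
        ok_k <- all(f2[kidx] > 0.05) && s2 > 0
        if (ok_k) {
          m2 <- unpack_parameters(f2, model, cmap)
          c2 <- sf_atom_contributions(m2, geom)
          Fc_2 <- rowSums(c2)
          Fc2_2 <- Mod(Fc_2)^2
          r2 <- sw * (Fo2 - s2 * Fc2_2)
          if (sum(r2^2) < sse) {
            model <- m2; fvec <- f2; scale <- s2
            contrib <- c2; Fc <- Fc_2; Fc2 <- Fc2_2
            resid <- r2; sse <- sum(r2^2)
            lambda <- max(lambda * 0.3, 1e-12)
            improved <- TRUE
            break
          }
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e10) break
    }
    gof2 <- sse / max(n - npar, 1)
    covm <- tryCatch(solve(JtJ) * gof2, error = function(e) {
      ## ill-conditioned normal matrix: pseudo-inverse variances
      sv2 <- svd(JtJ)
      dinv <- ifelse(sv2$d > sv2$d[1] * 1e-14, 1 / sv2$d, 0)
      (sv2$v %*% (dinv * t(sv2$u))) * gof2
    })
    su <- sqrt(pmax(diag(covm)[seq_along(sel)], 0))
    ## essentially exact fit (noise-free data): nothing left to move
    if (sse <= 1e-16 * sum((sw * Fo2)^2)) { converged <- TRUE; break }
    if (improved) {
      shift_esd <- abs(delta[seq_along(sel)]) /
        pmax(su, .Machine$double.eps)
      if (!any(is.na(shift_esd)) && max(shift_esd) < step$tol) {
        converged <- TRUE; break
      }
    } else {
      ## no downhill step found: converged in place if the gradient is
      ## negligible against the residual scale, else flag non-convergence
      converged <- sqrt(sum(g^2)) < 1e-6 * max(sqrt(sse), .Machine$double.eps)
      break
    }
  }
  gof <- sqrt(sse / max(n - npar, 1))
  Fo <- sqrt(pmax(Fo2, 0))
  Fcal <- sqrt(scale) * Mod(Fc)
  structure(list(model = model, cmap = cmap, scale = scale,
                 free = stats::setNames(fvec, cmap$free_names),
                 selected = selnames,
                 su = stats::setNames(su, selnames),
                 r_f = sum(abs(Fo - Fcal)) / sum(Fo),
                 r_f2 = sum(abs(Fo2 - scale * Fc2)) / sum(abs(Fo2)),
                 gof = gof, cycles = cycles, converged = converged,
                 condition = cond, n_obs = n, n_par = npar,
                 step = step$name),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit '%s': R(F)=%.4f R(F2)=%.4f GoF=%.3f  %d par / %d obs  %d cycles%s\n",
              x$step, x$r_f, x$r_f2, x$gof, x$n_par, x$n_obs, x$cycles,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Run an ordered refinement strategy
#'
#' Executes the steps in sequence, each starting from the previous step's
#' refined model, honouring per-step data filters (e.g. a high-order
#' heavy-atom step or a low-order H step) and constraint edits.
#'
#' @param model starting [crystal_model()].
#' @param data a [reflection_set()].
#' @param strategy list of [strategy_step()]s (may be empty).
#' @return list of `fit_result`s (empty strategy: empty list).
#' @export
staged_refinement <- function(model, data, strategy) {
  fits <- list()
  for (step in strategy) {
    fit <- lsq_refine(model, data, step)
    model <- fit$model
    fits[[step$name]] <- fit
  }
  fits
}

#' Standard X-H distances from neutron diffraction
#'
#' Bundled typical values (angstrom) used to reposition H atoms along
#' their X-H bond vectors; editable via the `table` argument of
#' [set_neutron_distances()].
#' @return named numeric vector (names are parent elements).
#' @export
neutron_distance_table <- function() {
  c(C = 1.083, N = 1.009, O = 0.983, B = 1.185)
}

#' Move H atoms to neutron-determined bond distances
#'
#' Each H atom is moved along its parent-to-H vector (parent = nearest
#' non-H atom, required within 1.3 angstrom) so that the X-H distance
#' equals the tabulated neutron value; the bond direction is preserved.
#'
#' @param model a [crystal_model()].
#' @param table named distances per parent element (angstrom).
#' @return updated model.
#' @export
set_neutron_distances <- function(model, table = neutron_distance_table()) {
  labs <- names(model$atoms)
  cart <- do.call(rbind, lapply(model$atoms, function(a)
    frac_to_cart(model$cell, a$xyz)))
  for (i in seq_along(labs)) {
    a <- model$atoms[[i]]
    if (a$element != "H") next
    best <- NULL; bestd <- Inf
    for (j in seq_along(labs)) {
      if (i == j || model$atoms[[j]]$element == "H") next
      d <- sqrt(sum((cart[i, ] - cart[j, ])^2))
      if (d < bestd) { bestd <- d; best <- j }
    }
    if (is.null(best) || bestd > 1.3)
      stop("H atom ", a$label, " has no parent atom within 1.3 A")
    parent <- model$atoms[[best]]
    target <- table[[parent$element]]
    if (is.null(target)) stop("no neutron distance for parent element ",
                              parent$element)
    v <- cart[i, ] - cart[best, ]
    newpos <- cart[best, ] + v / bestd * target
    model$atoms[[i]]$xyz <- as.numeric(cart_to_frac(model$cell, newpos))
  }
  model
}

#' Write a refinement strategy to a YAML file
#' @param strategy list of [strategy_step()]s.
#' @param path output path.
#' @export
write_strategy <- function(strategy, path) {
  yaml::write_yaml(lapply(strategy, function(s) {
    out <- s[!vapply(s, is.null, logical(1))]
    class(out) <- NULL
    if (!is.null(out$release_lsym)) out$release_lsym <- as.list(out$release_lsym)
    out
  }), path)
  invisible(path)
}

#' Read a refinement strategy from a YAML file
#' @param path file written by [write_strategy()] (or hand-authored).
#' @return list of [strategy_step()]s.
#' @export
read_strategy <- function(path) {
  lapply(yaml::read_yaml(path), function(s)
    strategy_step(s$name, unlist(s$classes),
                  atoms = if (!is.null(s$atoms)) unlist(s$atoms),
                  filter = s$filter %||% "all", cut = s$cut,
                  release_lsym = if (!is.null(s$release_lsym)) unlist(s$release_lsym),
                  release_ties = isTRUE(s$release_ties),
                  add_c3 = if (!is.null(s$add_c3)) unlist(s$add_c3),
                  fix_params = if (!is.null(s$fix_params)) unlist(s$fix_params),
                  max_cycles = s$max_cycles %||% 50, tol = s$tol %||% 0.01))
}
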