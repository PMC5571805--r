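## Static model electron density, density/error grids, Gaussian cube I/O,
## Gram-Charlier pdf checks and bond-critical-point search.
##
## The static density of one atom (thermally unsmeared, the usual
## convention for property maps) is
##   rho(d) = sum_core n_el R_sh(d)/(4 pi) + P_v kappa^3 R_v(kappa d)/(4 pi)
##            + sum_lm P_lm kappa'^3 R_l(kappa' d) Y_lm(d^ in local frame),
## the exact Fourier mate of the scattering-factor expression, so the
## grid-FT cross-check ties the two code paths together.

## symmetry images of all atoms whose density can reach any of `points`
## (Cartesian rows) within `rcut` angstrom
density_images <- function(model, points, rcut = 6, exclude_H = FALSE) {
  cell <- model$cell
  lo <- apply(points, 2, min) - rcut
  hi <- apply(points, 2, max) + rcut
  ## lattice translation search range from bounding box in fractional space
  corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]), c(lo[3], hi[3])))
  fr <- cart_to_frac(cell, corners)
  tr <- lapply(1:3, function(i) seq(floor(min(fr[, i])) - 1, ceiling(max(fr[, i])) + 1))
  shifts <- as.matrix(expand.grid(tr[[1]], tr[[2]], tr[[3]]))
  images <- list()
  Minv <- solve(cell$M)
  for (a in model$atoms) {
    if (exclude_H && a$element == "H") next
    frame <- local_frame(model, a)
    for (op in model$spacegroup$ops) {
      xf <- (as.numeric(op$R %*% a$xyz) + op$t) %% 1
      Rc <- cell$M %*% op$R %*% Minv
      frame_g <- Rc %*% frame
      for (si in seq_len(nrow(shifts))) {
        xs <- xf + as.numeric(shifts[si, ])
        pc <- as.numeric(frac_to_cart(cell, xs))
        if (all(pc > lo - 1e-9) && all(pc < hi + 1e-9))
          images[[length(images) + 1]] <-
            list(atom = a, pos = pc, frame = frame_g)
      }
    }
  }
  images
}

## density contribution of a single image evaluated at Cartesian points
image_density <- function(img, points, rcut = 6) {
  a <- img$atom
  e <- element_entry(a$element)
  d <- sweep(points, 2, img$pos)
  r <- sqrt(rowSums(d * d))
  out <- numeric(length(r))
  sel <- r <= rcut
  if (!any(sel)) return(out)
  rs <- r[sel]
  val <- numeric(length(rs))
  for (sh in e$core)
    val <- val + sh$nel * slater_radial(density_zeta(sh$zeta), sh$n, rs) / (4 * pi)
  zv <- density_zeta(e$valence$zeta)
  val <- val + a$Pv * a$kappa^3 *
    slater_radial(zv, e$valence$n, a$kappa * rs) / (4 * pi)
  nz <- which(a$Plm != 0)
  if (length(nz)) {
    u <- d[sel, , drop = FALSE] / pmax(rs, 1e-12)
    ul <- u %*% img$frame
    nms <- PLM_NAMES[nz]
    Y <- real_spherical_harmonics(ul, nms)
    kp <- a$kappa_prime
    zl <- density_zeta(e$def_zeta)
    ls <- as.integer(substr(nms, 2, 2))
    for (j in seq_along(nz)) {
      l <- ls[j]
      val <- val + a$Plm[nz[j]] * kp^3 *
        slater_radial(zl, e$def_n[l], kp * rs) * Y[, j]
    }
  }
  out[sel] <- a$occupancy * val
  out
}

#' Static model electron density at Cartesian points
#'
#' @param model a [crystal_model()].
#' @param points n x 3 matrix of Cartesian coordinates (angstrom).
#' @param exclude_H skip hydrogen atoms.
#' @param rcut per-atom density cutoff radius (angstrom).
#' @return numeric vector of densities (e/A^3).
#' @export
model_density <- function(model, points, exclude_H = FALSE, rcut = 6) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 3)
  imgs <- density_images(model, points, rcut, exclude_H)
  out <- numeric(nrow(points))
  for (img in imgs) out <- out + image_density(img, points, rcut)
  out
}

#' Static density sampled on a grid over one unit cell
#'
#' Samples the periodic model density on an n1 x n2 x n3 grid of the cell
#' (cell-axis fractions i/n), the layout expected by a discrete Fourier
#' transform of the cell contents.
#'
#' @param model a [crystal_model()].
#' @param n grid counts per axis (length 1 or 3).
#' @param rcut density cutoff radius (angstrom).
#' @return 3-D array of densities (e/A^3), first index fastest along a.
#' @export
sample_cell_density <- function(model, n, rcut = 6) {
  n <- rep(n, length.out = 3)
  fr <- as.matrix(expand.grid((seq_len(n[1]) - 1) / n[1],
                              (seq_len(n[2]) - 1) / n[2],
                              (seq_len(n[3]) - 1) / n[3]))
  pts <- frac_to_cart(model$cell, fr)
  rho <- model_density(model, pts, rcut = rcut)
  array(rho, dim = n)
}

#' Model density on an axis-aligned Cartesian grid
#'
#' @param model a [crystal_model()].
#' @param origin Cartesian origin (angstrom); default: bounding box of the
#'   non-H atoms minus `margin`.
#' @param npts counts per axis (>= 2); default from `spacing`.
#' @param spacing grid step (angstrom), default 0.1.
#' @param margin box margin around the non-H atoms (angstrom).
#' @param exclude_H exclude hydrogen density (default TRUE, the standard
#'   practice for property/error maps).
#' @return object of class `density_grid`: `origin`, `axes` (3x3, rows are
#'   step vectors), `npts`, `values` (3-D array, e/A^3).
#' @export
density_grid <- function(model, origin = NULL, npts = NULL, spacing = 0.1,
                         margin = 2.5, exclude_H = TRUE) {
  atoms <- Filter(function(a) !(exclude_H && a$element == "H"), model$atoms)
  if (!length(atoms)) stop("no atoms to map")
  pos <- do.call(rbind, lapply(atoms, function(a) frac_to_cart(model$cell, a$xyz)))
  if (is.null(origin)) origin <- apply(pos, 2, min) - margin
  if (is.null(npts)) {
    ext <- apply(pos, 2, max) + margin - origin
    npts <- pmax(2, ceiling(ext / spacing) + 1)
  }
  npts <- rep(npts, length.out = 3)
  if (any(npts < 2)) stop("grid needs at least 2 points per axis")
  axes <- diag(rep(spacing, 3))
  g <- as.matrix(expand.grid(seq_len(npts[1]) - 1, seq_len(npts[2]) - 1,
                             seq_len(npts[3]) - 1))
  pts <- sweep(g %*% axes, 2, origin, `+`)
  rho <- model_density(model, pts, exclude_H = exclude_H)
  structure(list(origin = origin, axes = axes, npts = npts,
                 values = array(rho, dim = npts)),
            class = "density_grid")
}

#' Pointwise standard-deviation (error) cube across k density grids
#'
#' @param grids list of `density_grid`s with identical geometry.
#' @return `density_grid` of pointwise sample standard deviations
#'   (denominator k - 1).
#' @export
error_cube <- function(grids) {
  if (length(grids) < 2) stop("need at least two grids")
  g0 <- grids[[1]]
  for (g in grids[-1]) {
    if (!isTRUE(all.equal(g$origin, g0$origin, tolerance = 1e-9)) ||
        !isTRUE(all.equal(g$axes, g0$axes, tolerance = 1e-9)) ||
        !identical(g$npts, g0$npts))
      stop("grid geometries differ")
  }
  k <- length(grids)
  mean_v <- Reduce(`+`, lapply(grids, `[[`, "values")) / k
  ss <- Reduce(`+`, lapply(grids, function(g) (g$values - mean_v)^2))
  g0$values <- sqrt(ss / (k - 1))
  g0
}

#' Write a Gaussian cube file
#'
#' Header lengths are converted to Bohr per the cube standard; grid values
#' are written verbatim (e/A^3), z fastest. The documented default
#' iso-levels for overlays are 1.0, 1.5, 2.0 and 2.5 e/A^3.
#'
#' @param grid a `density_grid`.
#' @param path output path.
#' @param atoms optional matrix with columns Z, x, y, z (Cartesian
#'   angstrom) for the atom records.
#' @export
write_cube <- function(grid, path, atoms = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  na <- if (is.null(atoms)) 0L else nrow(atoms)
  writeLines(c("model density cube",
               "written by rcross"), con)
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", na,
                     grid$origin[1] / BOHR, grid$origin[2] / BOHR,
                     grid$origin[3] / BOHR), con)
  for (i in 1:3)
    writeLines(sprintf("%5d%12.6f%12.6f%12.6f", grid$npts[i],
                       grid$axes[i, 1] / BOHR, grid$axes[i, 2] / BOHR,
                       grid$axes[i, 3] / BOHR), con)
  if (na > 0)
    for (i in seq_len(na))
      writeLines(sprintf("%5d%12.6f%12.6f%12.6f%12.6f", as.integer(atoms[i, 1]),
                         0, atoms[i, 2] / BOHR, atoms[i, 3] / BOHR,
                         atoms[i, 4] / BOHR), con)
  v <- grid$values
  for (ix in seq_len(grid$npts[1])) for (iy in seq_len(grid$npts[2])) {
    row <- v[ix, iy, ]
    for (start in seq(1, length(row), by = 6)) {
      chunk <- row[start:min(start + 5, length(row))]
      writeLines(paste(sprintf("%13.5e", chunk), collapse = ""), con)
    }
  }
  invisible(path)
}

#' Read a Gaussian cube file written by [write_cube()]
#'
#' @param path cube file path.
#' @return a `density_grid` (lengths converted back to angstrom).
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6) stop("malformed cube header: fewer than 6 lines")
  parse_rec <- function(i) {
    x <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]))
    if (any(is.na(x)) || length(x) < 4)
      stop("malformed cube header at line ", i)
    x
  }
  h0 <- parse_rec(3)
  na <- abs(as.integer(h0[1]))
  origin <- h0[2:4] * BOHR
  npts <- integer(3); axes <- matrix(0, 3, 3)
  for (i in 1:3) {
    hi <- parse_rec(3 + i)
    npts[i] <- as.integer(hi[1])
    axes[i, ] <- hi[2:4] * BOHR
  }
  vals <- as.numeric(unlist(strsplit(trimws(lines[(7 + na):length(lines)]),
                                     "[[:space:]]+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(npts))
    stop("cube value count ", length(vals), " != ", prod(npts))
  v <- array(0, dim = npts)
  ii <- 1
  for (ix in seq_len(npts[1])) for (iy in seq_len(npts[2])) {
    v[ix, iy, ] <- vals[ii:(ii + npts[3] - 1)]
    ii <- ii + npts[3]
  }
  structure(list(origin = origin, axes = axes, npts = npts, values = v),
            class = "density_grid")
}

## ---- Gram-Charlier probability density function ----

## fractional displacement covariance: <u_i u_j> = U_ij a*_i a*_j
frac_covariance <- function(atom, cell) {
  astar <- sqrt(diag(cell$Gstar))
  Um <- matrix(c(atom$U[1], atom$U[4], atom$U[5],
                 atom$U[4], atom$U[2], atom$U[6],
                 atom$U[5], atom$U[6], atom$U[3]), 3, 3)
  (astar %o% astar) * Um
}

#' Evaluate the Gram-Charlier displacement pdf of an atom
#'
#' The third-order Gram-Charlier pdf is the harmonic Gaussian times
#' `1 + (1/6) C_jkl H_jkl(u)` (Hermite polynomials in the inverse
#' covariance metric). A harmonic atom has a strictly non-negative pdf;
#' large C3 drive it negative, which is the telltale check for an
#' unphysical anharmonic refinement. The pdf is integrated on a regular
#' grid over +-`extent` standard deviations.
#'
#' @param atom an [mm_atom()] with positive-definite U.
#' @param cell a [unit_cell()].
#' @param n grid points per axis (odd recommended).
#' @param extent half-width in standard deviations.
#' @return list: `min` (lowest pdf value, A^-3), `neg_percent` (100 x
#'   integral of the negative part), `total` (integral, ~1), `grid_frac`
#'   (the fractional grid spec, for reuse).
#' @export
pdf_eval <- function(atom, cell, n = 41, extent = 5) {
  S <- frac_covariance(atom, cell)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("U tensor is not positive definite")
  Sinv <- solve(S)
  sd_ax <- sqrt(diag(S))
  ax <- lapply(1:3, function(i) seq(-extent * sd_ax[i], extent * sd_ax[i],
                                    length.out = n))
  gg <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  w <- gg %*% Sinv
  q <- rowSums(w * gg)
  norm <- (2 * pi)^(-1.5) / sqrt(det(S))
  p <- norm * exp(-0.5 * q)
  if (any(atom$C3 != 0)) {
    herm <- numeric(nrow(gg))
    for (k in which(atom$C3 != 0)) {
      ix <- C3_IDX[[k]]
      h3 <- w[, ix[1]] * w[, ix[2]] * w[, ix[3]] -
        (w[, ix[1]] * Sinv[ix[2], ix[3]] +
         w[, ix[2]] * Sinv[ix[1], ix[3]] +
         w[, ix[3]] * Sinv[ix[1], ix[2]])
      herm <- herm + C3_MULT[k] * atom$C3[k] * h3
    }
    p <- p * (1 + herm / 6)
  }
  voxel <- prod(vapply(ax, function(a) a[2] - a[1], numeric(1)))
  vol <- cell$volume
  list(min = min(p) / vol,
       neg_percent = 100 * sum(pmax(-p, 0)) * voxel,
       total = sum(p) * voxel,
       grid_frac = ax)
}

## Fourier transform of the pdf on its grid: T(h) = sum p(u) e^{2 pi i h.u}
pdf_fourier <- function(atom, cell, hkl, n = 61, extent = 6) {
  pe_ax <- pdf_eval(atom, cell, n = n, extent = extent)
  ax <- pe_ax$grid_frac
  gg <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  S <- frac_covariance(atom, cell)
  Sinv <- solve(S)
  w <- gg %*% Sinv
  q <- rowSums(w * gg)
  norm <- (2 * pi)^(-1.5) / sqrt(det(S))
  p <- norm * exp(-0.5 * q)
  if (any(atom$C3 != 0)) {
    herm <- numeric(nrow(gg))
    for (k in which(atom$C3 != 0)) {
      ix <- C3_IDX[[k]]
      h3 <- w[, ix[1]] * w[, ix[2]] * w[, ix[3]] -
        (w[, ix[1]] * Sinv[ix[2], ix[3]] +
         w[, ix[2]] * Sinv[ix[1], ix[3]] +
         w[, ix[3]] * Sinv[ix[1], ix[2]])
      herm <- herm + C3_MULT[k] * atom$C3[k] * h3
    }
    p <- p * (1 + herm / 6)
  }
  voxel <- prod(vapply(ax, function(a) a[2] - a[1], numeric(1)))
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  vapply(seq_len(nrow(h)), function(i) {
    ph <- exp(2i * pi * as.numeric(gg %*% h[i, ]))
    sum(p * ph) * voxel
  }, complex(1))
}

## ---- bond critical points ----

num_gradient <- function(f, x, h = 1e-5) {
  g <- numeric(3)
  for (i in 1:3) {
    e <- numeric(3); e[i] <- h
    g[i] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  g
}

#' Finite-difference Hessian of a scalar field
#' @param f function of a length-3 Cartesian position.
#' @param x evaluation point.
#' @param h central-difference step (angstrom).
#' @return symmetric 3x3 matrix.
#' @export
density_hessian <- function(f, x, h = 1e-3) {
  H <- matrix(0, 3, 3)
  f0 <- f(x)
  for (i in 1:3) {
    ei <- numeric(3); ei[i] <- h
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    for (j in seq_len(i - 1)) {
      ej <- numeric(3); ej[j] <- h
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

#' Search for a bond critical point
#'
#' Newton iteration on the density gradient starting from the internuclear
#' midpoint (or a supplied start). Gradient and Hessian come from central
#' finite differences of the analytic static density. The converged point
#' is classified by its Hessian signature; a bond critical point has
#' signature (3, -1).
#'
#' @param model a [crystal_model()], or a density function of a length-3
#'   Cartesian position (for oracles).
#' @param pair character vector of two atom labels (when `model` is a
#'   crystal model); atoms must lie within 3 angstrom.
#' @param start optional Cartesian start (overrides the midpoint).
#' @param grad_tol convergence threshold on |grad rho| (e/A^4).
#' @param max_iter Newton iteration cap.
#' @param h_grad,h_hess finite-difference steps (angstrom).
#' @return object of class `critical_point`: `position`, `rho`,
#'   `laplacian`, `eigenvalues`, `ellipticity`, `signature`, `is_bcp`.
#' @export
find_bcp <- function(model, pair = NULL, start = NULL, grad_tol = 1e-8,
                     max_iter = 100, h_grad = 2e-5, h_hess = 1e-3) {
  if (is.function(model)) {
    f <- model
    if (is.null(start)) stop("a start point is required with a density function")
    x <- start
  } else {
    if (is.null(pair) && is.null(start)) stop("give an atom pair or a start")
    f <- function(x) model_density(model, matrix(x, 1, 3))
    if (is.null(start)) {
      p1 <- as.numeric(frac_to_cart(model$cell, model$atoms[[pair[1]]]$xyz))
      p2 <- as.numeric(frac_to_cart(model$cell, model$atoms[[pair[2]]]$xyz))
      if (sqrt(sum((p1 - p2)^2)) > 3)
        stop("atoms ", pair[1], " and ", pair[2], " are more than 3 A apart")
      x <- (p1 + p2) / 2
    } else x <- start
  }
  for (it in seq_len(max_iter)) {
    g <- num_gradient(f, x, h_grad)
    if (sqrt(sum(g^2)) < grad_tol) break
    H <- density_hessian(f, x, h_hess)
    step <- tryCatch(solve(H, -g), error = function(e) -g)
    ns <- sqrt(sum(step^2))
    if (ns > 0.3) step <- step * 0.3 / ns   # trust region: 0.3 A
    x <- x + step
    if (it == max_iter) stop("critical-point search did not converge in ",
                             max_iter, " iterations")
  }
  H <- density_hessian(f, x, h_hess)
  ev <- sort(eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  sig <- sum(sign(ev))
  lam <- sort(ev)                      # lam1 <= lam2 <= lam3
  eps <- if (lam[2] != 0) abs(lam[1]) / abs(lam[2]) - 1 else NA_real_
  structure(list(position = x, rho = f(x), laplacian = sum(ev),
                 eigenvalues = lam, ellipticity = eps,
                 signature = c(3, sig), is_bcp = (lam[1] < 0 && lam[2] < 0 && lam[3] > 0),
                 grad_norm = sqrt(sum(num_gradient(f, x, h_grad)^2))),
            class = "critical_point")
}

#' @export
print.critical_point <- function(x, ...) {
  cat(sprintf("critical point (3,%+d)%s at (%.4f %.4f %.4f) A\n",
              x$signature[2], if (x$is_bcp) " [BCP]" else "",
              x$position[1], x$position[2], x$position[3]))
  cat(sprintf("  rho = %.4f e/A^3, lap = %.4f e/A^5, eps = %.4f\n",
              x$rho, x$laplacian, x$ellipticity))
  invisible(x)
}

#' Distribution of bond-critical-point properties across k models
#'
#' Locates the BCP of each atom pair in the all-data model and in each of
#' the k cross-validation models, and tabulates, per property (rho,
#' Laplacian, ellipticity), v_total, v_mean, s_mean, |v_mean -
#' v_total|/s_mean and the Shapiro-Wilk normality statistics of the
#' k-member distribution. s_mean is a lower limit for the property's true
#' uncertainty because the k refinements are not independent.
#'
#' @param models list of k [crystal_model()]s (the CV members).
#' @param total_model the all-data model.
#' @param pairs list of 2-element atom-label vectors.
#' @return data.frame, one row per (pair, property); pairs whose BCP search
#'   fails in any member are flagged and excluded.
#' @export
bcp_distribution <- function(models, total_model, pairs) {
  rows <- list()
  for (pr in pairs) {
    tot <- tryCatch(find_bcp(total_model, pr), error = function(e) NULL)
    mem <- lapply(models, function(m)
      tryCatch(find_bcp(m, pr), error = function(e) NULL))
    lab <- paste(pr, collapse = "-")
    if (is.null(tot) || any(vapply(mem, is.null, logical(1)))) {
      rows[[length(rows) + 1]] <- data.frame(
        bond = lab, property = NA_character_, v_total = NA_real_,
        v_mean = NA_real_, s_mean = NA_real_, dev_rel = NA_real_,
        W = NA_real_, p = NA_real_, excluded = TRUE)
      next
    }
    for (prop in c("rho", "laplacian", "ellipticity")) {
      vt <- tot[[prop]]
      vi <- vapply(mem, `[[`, numeric(1), prop)
      sm <- if (length(vi) > 1) stats::sd(vi) else 0
      sw <- tryCatch(shapiro_wilk(vi), error = function(e) list(W = NA, p = NA))
      rows[[length(rows) + 1]] <- data.frame(
        bond = lab, property = prop, v_total = vt, v_mean = mean(vi),
        s_mean = sm, dev_rel = if (is.finite(sm) && sm > 0) abs(mean(vi) - vt) / sm else 0,
        W = sw$W, p = sw$p, excluded = FALSE)
    }
  }
  do.call(rbind, rows)
}
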