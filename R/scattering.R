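## Hansen-Coppens structure-factor engine.
##
## Per atom and reflection the scattering amplitude is
##   f = f_core(s) + P_v f_val(s/kappa)
##       + sum_l 4 pi i^l <j_l>(s/kappa') sum_m P_lm Y_lm(h^ in local frame)
## multiplied by the displacement factor
##   T(h) = exp(-2 pi^2 h_i h_j a*_i a*_j U_ij)
##          * [1 - i (4 pi^3 / 3) C_jkl h_j h_k h_l]
## (third-order Gram-Charlier, International Tables convention), and summed
## over symmetry copies with h' = h R and phase exp(2 pi i h.(R x + t)).

TWO_PI <- 2 * pi

## quadratic form h' beta h' with beta_ij = 2 pi^2 a*_i a*_j U_ij
harmonic_exponent <- function(hR, U, astar) {
  Um <- matrix(c(U[1], U[4], U[5],
                 U[4], U[2], U[6],
                 U[5], U[6], U[3]), 3, 3)
  B <- 2 * pi^2 * (astar %o% astar) * Um
  rowSums((hR %*% B) * hR)
}

psd_project_U <- function(U, astar) {
  Um <- matrix(c(U[1], U[4], U[5],
                 U[4], U[2], U[6],
                 U[5], U[6], U[3]), 3, 3)
  S <- (astar %o% astar) * Um
  ev <- eigen(S, symmetric = TRUE)
  if (all(ev$values >= -1e-12)) return(U)
  warning("non-positive-semidefinite U projected to nearest PSD tensor")
  lam <- pmax(ev$values, 0)
  S2 <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
  Um2 <- S2 / (astar %o% astar)
  stats::setNames(c(Um2[1,1], Um2[2,2], Um2[3,3], Um2[1,2], Um2[1,3], Um2[2,3]),
                  U_NAMES)
}

## C_jkl h_j h_k h_l contraction over the ten unique components
c3_contraction <- function(hR, C3) {
  acc <- numeric(nrow(hR))
  nz <- which(C3 != 0)
  for (k in nz) {
    ix <- C3_IDX[[k]]
    acc <- acc + C3_MULT[k] * C3[k] * hR[, ix[1]] * hR[, ix[2]] * hR[, ix[3]]
  }
  acc
}

#' Atomic displacement factor T(h)
#'
#' Harmonic Debye-Waller factor times the third-order Gram-Charlier
#' correction. With all C3 zero the factor is real; U = 0 and C3 = 0 give
#' T = 1.
#'
#' @param atom an [mm_atom()].
#' @param hkl n x 3 index matrix (or length-3 vector).
#' @param cell a [unit_cell()].
#' @return complex vector of length n.
#' @export
displacement_factor <- function(atom, hkl, cell) {
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  astar <- sqrt(diag(cell$Gstar))
  U <- psd_project_U(atom$U, astar)
  Th <- exp(-harmonic_exponent(h, U, astar))
  if (any(atom$C3 != 0)) {
    gc <- c3_contraction(h, atom$C3)
    Th <- Th * complex(real = 1, imaginary = -(4 * pi^3 / 3) * gc)
  }
  as.complex(Th)
}

#' Aspherical atomic scattering factor
#'
#' Scattering amplitude of one multipole atom (without displacement factor
#' or site phase), evaluated in the given local frame. Reduces exactly to
#' [iam_form_factor()] when all deformation populations vanish, kappa = 1
#' and P_v equals the neutral valence count.
#'
#' @param atom an [mm_atom()].
#' @param hkl n x 3 index matrix.
#' @param cell a [unit_cell()].
#' @param frame 3 x 3 matrix whose columns are the local axes in Cartesian
#'   coordinates (default identity).
#' @return complex vector (electrons).
#' @export
atomic_scattering <- function(atom, hkl, cell, frame = diag(3)) {
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  s <- stol(cell, h)
  hc <- hkl_cart(cell, h)
  e <- element_entry(atom$element)
  if (atom$kappa <= 0 || atom$kappa_prime <= 0) stop("kappa must be positive")
  f <- core_form_factor(e, s) + atom$Pv * valence_form_factor(e, s, atom$kappa)
  f <- as.complex(f)
  nz <- which(atom$Plm != 0)
  if (length(nz)) {
    nrm <- sqrt(rowSums(hc^2))
    ok <- nrm > 1e-12
    u <- hc[ok, , drop = FALSE] / nrm[ok]
    ul <- u %*% frame
    nms <- PLM_NAMES[nz]
    Y <- real_spherical_harmonics(ul, nms)
    ls <- as.integer(substr(nms, 2, 2))
    for (j in seq_along(nz)) {
      l <- ls[j]
      jl <- fourier_bessel(l, density_zeta(e$def_zeta), e$def_n[l],
                           s[ok] / atom$kappa_prime)
      f[ok] <- f[ok] + (4 * pi * (1i)^l) * atom$Plm[nz[j]] * jl * Y[, j]
    }
  }
  f
}

## geometry cache shared by all structure-factor evaluations on one
## (cell, space group, hkl) triple
sf_geometry <- function(cell, spacegroup, hkl) {
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  s <- stol(cell, h)
  astar <- sqrt(diag(cell$Gstar))
  ops <- spacegroup$ops
  per_op <- lapply(ops, function(op) {
    hR <- h %*% op$R
    hc <- hkl_cart(cell, hR)
    nrm <- sqrt(rowSums(hc^2))
    u <- hc / pmax(nrm, 1e-300)
    list(hR = hR, u = u, ht = as.numeric(h %*% op$t), t = op$t, R = op$R)
  })
  list(hkl = h, s = s, astar = astar, per_op = per_op, n = nrow(h))
}

## per-atom structure-factor contributions (summed over symmetry copies):
## complex matrix n_refl x n_atoms
sf_atom_contributions <- function(model, geom, atoms = NULL) {
  labels <- if (is.null(atoms)) names(model$atoms) else atoms
  out <- matrix(0i, geom$n, length(labels))
  colnames(out) <- labels
  for (j in seq_along(labels)) {
    a <- model$atoms[[labels[j]]]
    e <- element_entry(a$element)
    frame <- local_frame(model, a)
    U <- psd_project_U(a$U, geom$astar)
    f_sph <- core_form_factor(e, geom$s) +
      a$Pv * valence_form_factor(e, geom$s, a$kappa)
    nz <- which(a$Plm != 0)
    nms <- PLM_NAMES[nz]
    ls <- as.integer(substr(nms, 2, 2))
    jl_cache <- list()
    for (l in unique(ls))
      jl_cache[[as.character(l)]] <-
        fourier_bessel(l, density_zeta(e$def_zeta), e$def_n[l],
                       geom$s / a$kappa_prime)
    has_c3 <- any(a$C3 != 0)
    acc <- complex(geom$n)
    for (po in geom$per_op) {
      Th <- exp(-harmonic_exponent(po$hR, U, geom$astar))
      Tc <- if (has_c3) {
        gc <- c3_contraction(po$hR, a$C3)
        Th * complex(real = 1, imaginary = -(4 * pi^3 / 3) * gc)
      } else as.complex(Th)
      fa <- as.complex(f_sph)
      if (length(nz)) {
        ul <- po$u %*% frame
        Y <- real_spherical_harmonics(ul, nms)
        small <- geom$s < 1e-12
        for (jj in seq_along(nz)) {
          l <- ls[jj]
          term <- (4 * pi * (1i)^l) * a$Plm[nz[jj]] *
            jl_cache[[as.character(l)]] * Y[, jj]
          if (any(small)) term[small] <- 0
          fa <- fa + term
        }
      }
      phase <- exp(TWO_PI * 1i * (rowSums(po$hR * matrix(a$xyz, geom$n, 3, byrow = TRUE)) + po$ht))
      acc <- acc + fa * Tc * phase
    }
    out[, j] <- a$occupancy * acc
  }
  out
}

#' Structure factors of a model
#'
#' F(h) = sum over symmetry operations and atoms of
#' occ * f(hR) * T(hR) * exp(2 pi i h.(Rx + t)). F(0,0,0) equals the total
#' electron count of the cell contents.
#'
#' @param model a [crystal_model()].
#' @param hkl n x 3 index matrix (or length-3 vector).
#' @param geom optional geometry cache from a previous call on the same
#'   cell/space group/hkl (internal speed-up).
#' @return complex vector of structure factors (electrons).
#' @export
structure_factor <- function(model, hkl, geom = NULL) {
  if (is.null(geom)) geom <- sf_geometry(model$cell, model$spacegroup, hkl)
  rowSums(sf_atom_contributions(model, geom))
}

## Analytic structure-factor derivatives. For each atom the per-symop
## factorization  base = occ * f * T * phase  gives closed-form derivatives
## with respect to xyz (phase), U (harmonic exponent), C3 (Gram-Charlier
## term), Pv and P_lm (linear); only kappa and kappa' need finite
## differences. Returns the per-atom contributions plus a complex matrix
## of dF/dp columns for the requested full parameters.
sf_model_derivs <- function(model, geom, rows) {
  labels <- names(model$atoms)
  contrib <- matrix(0i, geom$n, length(labels))
  colnames(contrib) <- labels
  want <- split(sub("^[^.]+\\.", "", rows), sub("\\..*$", "", rows))
  derivs <- matrix(0i, geom$n, length(rows))
  colnames(derivs) <- rows
  gamma3 <- 4 * pi^3 / 3
  for (j in seq_along(labels)) {
    lab <- labels[j]
    a <- model$atoms[[lab]]
    e <- element_entry(a$element)
    frame <- local_frame(model, a)
    U <- psd_project_U(a$U, geom$astar)
    wn <- want[[lab]]
    f_val <- valence_form_factor(e, geom$s, a$kappa)
    f_sph <- core_form_factor(e, geom$s) + a$Pv * f_val
    need_pops <- any(wn %in% PLM_NAMES)
    nzp <- union(which(a$Plm != 0),
                 if (need_pops) match(intersect(wn, PLM_NAMES), PLM_NAMES) else integer(0))
    nzp <- sort(nzp)
    nms <- PLM_NAMES[nzp]
    ls <- as.integer(substr(nms, 2, 2))
    jl_cache <- list()
    for (l in unique(ls))
      jl_cache[[as.character(l)]] <-
        fourier_bessel(l, density_zeta(e$def_zeta), e$def_n[l],
                       geom$s / a$kappa_prime)
    has_c3 <- any(a$C3 != 0) || any(wn %in% C3_NAMES)
    acc <- complex(geom$n)
    small <- geom$s < 1e-12
    for (po in geom$per_op) {
      Th <- exp(-harmonic_exponent(po$hR, U, geom$astar))
      gc <- if (has_c3) c3_contraction(po$hR, a$C3) else NULL
      Tc <- if (has_c3) Th * complex(real = 1, imaginary = -gamma3 * gc)
            else as.complex(Th)
      Y <- NULL
      if (length(nzp)) {
        ul <- po$u %*% frame
        Y <- real_spherical_harmonics(ul, nms)
      }
      fa <- as.complex(f_sph)
      if (length(nzp)) {
        act <- which(a$Plm[nzp] != 0)
        for (jj in act) {
          term <- (4 * pi * (1i)^ls[jj]) * a$Plm[nzp[jj]] *
            jl_cache[[as.character(ls[jj])]] * Y[, jj]
          term[small] <- 0
          fa <- fa + term
        }
      }
      phase <- exp(TWO_PI * 1i *
                   (rowSums(po$hR * matrix(a$xyz, geom$n, 3, byrow = TRUE)) + po$ht))
      pre <- a$occupancy * phase
      base <- pre * fa * Tc
      acc <- acc + base
      for (p in wn) {
        col <- paste(lab, p, sep = ".")
        dv <- if (p %in% c("x", "y", "z")) {
          i <- match(p, c("x", "y", "z"))
          TWO_PI * 1i * po$hR[, i] * base
        } else if (p %in% U_NAMES) {
          k <- match(p, U_NAMES)
          ij <- list(c(1,1), c(2,2), c(3,3), c(1,2), c(1,3), c(2,3))[[k]]
          mult <- if (ij[1] == ij[2]) 1 else 2
          -2 * pi^2 * geom$astar[ij[1]] * geom$astar[ij[2]] * mult *
            po$hR[, ij[1]] * po$hR[, ij[2]] * base
        } else if (p %in% C3_NAMES) {
          k <- match(p, C3_NAMES)
          ix <- C3_IDX[[k]]
          h3 <- C3_MULT[k] * po$hR[, ix[1]] * po$hR[, ix[2]] * po$hR[, ix[3]]
          pre * fa * Th * complex(imaginary = -gamma3 * h3)
        } else if (p == "Pv") {
          pre * f_val * Tc
        } else if (p %in% PLM_NAMES) {
          jj <- match(p, nms)
          term <- (4 * pi * (1i)^ls[jj]) * jl_cache[[as.character(ls[jj])]] * Y[, jj]
          term[small] <- 0
          pre * term * Tc
        } else next   # kappa, kappa_prime: finite differences upstream
        derivs[, col] <- derivs[, col] + dv
      }
    }
    contrib[, j] <- acc
  }
  list(contrib = contrib, F = rowSums(contrib), derivs = derivs)
}
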