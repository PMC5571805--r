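## Constraint machinery. The full parameter vector of a model concatenates,
## per atom: x, y, z, six U_ij, ten C3, Pv, 24 P_lm, kappa, kappa'.
## A constraint map expresses the full vector as an affine function of a
## free vector, p_full = A f + b, built from three constraint classes:
##   * local-symmetry masks (forbidden P_lm identically zero),
##   * special-position (site-stabilizer) linear constraints on xyz, U, C3
##     and P_lm, derived by numerical invariance projection, never from
##     hard-coded tables,
##   * chemical ties (atoms sharing Pv, P_lm, kappa, kappa').
## The map is normalized so that each free parameter equals one designated
## full component ("pivot"), which makes pack/unpack round-trips exact and
## the map idempotent.

ATOM_PARAM_NAMES <- c("x", "y", "z", U_NAMES, C3_NAMES, "Pv", PLM_NAMES,
                      "kappa", "kappa_prime")

param_class <- function(name) {
  if (name %in% c("x", "y", "z")) return("xyz")
  if (name %in% U_NAMES) return("U")
  if (name %in% C3_NAMES) return("C3")
  if (name == "Pv") return("M")
  if (name == "kappa") return("K")
  if (name == "kappa_prime") return("KP")
  l <- substr(name, 2, 2)
  c("1" = "D", "2" = "Q", "3" = "O", "4" = "H")[[l]]
}

#' Full parameter vector of a model
#' @param model a [crystal_model()].
#' @return named numeric vector (names `"<label>.<param>"`).
#' @export
full_params <- function(model) {
  out <- lapply(model$atoms, function(a)
    c(a$xyz, a$U, a$C3, a$Pv, a$Plm, a$kappa, a$kappa_prime))
  v <- unlist(out, use.names = FALSE)
  names(v) <- unlist(lapply(model$atoms, function(a)
    paste(a$label, ATOM_PARAM_NAMES, sep = ".")))
  v
}

#' Write a full parameter vector back into a model
#' @param model a [crystal_model()].
#' @param p vector as produced by [full_params()].
#' @return updated model.
#' @export
set_full_params <- function(model, p) {
  np <- length(ATOM_PARAM_NAMES)
  for (i in seq_along(model$atoms)) {
    blk <- p[((i - 1) * np + 1):(i * np)]
    a <- model$atoms[[i]]
    a$xyz <- unname(blk[1:3])
    a$U <- stats::setNames(unname(blk[4:9]), U_NAMES)
    a$C3 <- stats::setNames(unname(blk[10:19]), C3_NAMES)
    a$Pv <- unname(blk[20])
    a$Plm <- stats::setNames(unname(blk[21:44]), PLM_NAMES)
    a$kappa <- unname(blk[45])
    a$kappa_prime <- unname(blk[46])
    model$atoms[[i]] <- a
  }
  model
}

## ---- linear actions of a (fractional or local Cartesian) rotation ----

act_U <- function(R) {
  D <- matrix(0, 6, 6)
  for (k in 1:6) {
    M <- matrix(0, 3, 3)
    idx <- list(c(1,1), c(2,2), c(3,3), c(1,2), c(1,3), c(2,3))[[k]]
    M[idx[1], idx[2]] <- M[idx[2], idx[1]] <- 1
    Mp <- R %*% M %*% t(R)
    D[, k] <- c(Mp[1,1], Mp[2,2], Mp[3,3], Mp[1,2], Mp[1,3], Mp[2,3])
  }
  D
}

act_C3 <- function(R) {
  D <- matrix(0, 10, 10)
  for (k in 1:10) {
    Tk <- array(0, c(3, 3, 3))
    for (perm in unique(asplit(perms3(C3_IDX[[k]]), 1)))
      Tk[perm[1], perm[2], perm[3]] <- 1
    Tp <- array(0, c(3, 3, 3))
    for (j in 1:3) for (kk in 1:3) for (ll in 1:3) {
      s <- 0
      for (a in 1:3) for (b in 1:3) for (cc in 1:3)
        s <- s + R[j, a] * R[kk, b] * R[ll, cc] * Tk[a, b, cc]
      Tp[j, kk, ll] <- s
    }
    D[, k] <- vapply(C3_IDX, function(ix) Tp[ix[1], ix[2], ix[3]], numeric(1))
  }
  D
}

perms3 <- function(ix) {
  p <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  t(apply(p, 1, function(o) ix[o]))
}

act_Plm <- function(Rloc) {
  u <- probe_directions(80)
  B0 <- real_spherical_harmonics(u, PLM_NAMES)
  B1 <- real_spherical_harmonics(u %*% t(Rloc), PLM_NAMES)
  qr.solve(B0, B1)   # D with Y_i(R u) = sum_j D[j,i] Y_j(u) -> constraint D c = c
}

## null-space basis of stacked (D_g - I), pivot-normalized; NULL ops -> identity
invariant_basis <- function(Dlist, dim) {
  if (!length(Dlist)) return(list(B = diag(dim), piv = seq_len(dim)))
  S <- do.call(rbind, lapply(Dlist, function(D) D - diag(dim)))
  sv <- svd(S, nu = 0)
  nf <- sum(sv$d < 1e-8 * max(sv$d, 1))
  if (max(sv$d) < 1e-10) return(list(B = diag(dim), piv = seq_len(dim)))
  if (nf == 0) return(list(B = matrix(0, dim, 0), piv = integer(0)))
  B <- sv$v[, (ncol(sv$v) - nf + 1):ncol(sv$v), drop = FALSE]
  piv <- qr(t(B), LAPACK = TRUE)$pivot[seq_len(nf)]
  B <- B %*% solve(B[piv, , drop = FALSE])
  B[abs(B) < 1e-12] <- 0
  list(B = B, piv = sort(piv))
}

## re-normalize after sorting pivots
normalize_basis <- function(B, piv) {
  B <- B %*% solve(B[piv, , drop = FALSE])
  B[abs(B) < 1e-12] <- 0
  B
}

## ---- per-atom block construction ----

atom_blocks <- function(model, atom, use_lsym = TRUE, use_special = TRUE,
                        tol = 1e-4) {
  stab <- if (use_special) site_stabilizer(model$spacegroup, atom$xyz, tol) else
    list(list(R = diag(3L), t = numeric(3)))
  nontriv <- Filter(function(op) !all(op$R == diag(3)), stab)
  M <- model$cell$M
  A <- local_frame(model, atom)

  ## xyz: affine, offset = symmetrized position
  if (length(nontriv)) {
    Ls <- lapply(stab, function(op) round(as.numeric(op$R %*% atom$xyz) + op$t - atom$xyz))
    x0 <- Reduce(`+`, Map(function(op, L) as.numeric(op$R %*% atom$xyz) + op$t - L,
                          stab, Ls)) / length(stab)
    ib <- invariant_basis(lapply(nontriv, `[[`, "R"), 3)
    if (length(ib$piv)) ib$B <- normalize_basis(ib$B, ib$piv)
    b_xyz <- if (length(ib$piv)) x0 - ib$B %*% x0[ib$piv] else x0
    xyz_blk <- list(B = ib$B, piv = ib$piv, b = as.numeric(b_xyz))
  } else {
    xyz_blk <- list(B = diag(3), piv = 1:3, b = numeric(3))
  }

  ## U and C3: invariance under stabilizer rotations (fractional basis)
  ub <- invariant_basis(lapply(nontriv, function(op) act_U(op$R)), 6)
  if (length(ub$piv)) ub$B <- normalize_basis(ub$B, ub$piv)
  cb <- invariant_basis(lapply(nontriv, function(op) act_C3(op$R)), 10)
  if (length(cb$piv)) cb$B <- normalize_basis(cb$B, cb$piv)

  ## P_lm: local-symmetry ops (local frame) + stabilizer rotations
  Dl <- list()
  if (use_lsym && atom$local_symmetry != "none")
    Dl <- lapply(local_symmetry_ops(atom$local_symmetry), act_Plm)
  if (length(nontriv)) {
    Minv <- solve(M)
    for (op in nontriv) {
      Rc <- M %*% op$R %*% Minv          # Cartesian action
      Rloc <- t(A) %*% Rc %*% A          # in the atom's local frame
      Dl <- c(Dl, list(act_Plm(Rloc)))
    }
  }
  pb <- invariant_basis(Dl, 24)
  if (length(pb$piv)) pb$B <- normalize_basis(pb$B, pb$piv)

  list(xyz = xyz_blk,
       U = list(B = ub$B, piv = ub$piv, b = numeric(6)),
       C3 = list(B = cb$B, piv = cb$piv, b = numeric(10)),
       Plm = list(B = pb$B, piv = pb$piv, b = numeric(24)))
}

#' Build the constraint map of a model
#'
#' Assembles the affine map `p_full = A f + b` from local-symmetry masks,
#' special-position constraints and chemical ties (see package docs). The
#' free-parameter metadata records, for every free column, its parameter
#' class and the atoms it drives.
#'
#' @param model a [crystal_model()].
#' @param use_lsym apply local-symmetry multipole restrictions.
#' @param use_ties apply chemical ties.
#' @param use_special apply special-position constraints. Each default is
#'   taken from `model$constraint_options` when that field is set (the
#'   mistake scenarios switch constraint classes off model-wide).
#' @param tol special-position detection tolerance (fractional units).
#' @return object of class `constraint_map`.
#' @export
constraint_map <- function(model, use_lsym = NULL, use_ties = NULL,
                           use_special = NULL, tol = 1e-4) {
  opts <- model$constraint_options
  pick <- function(x, nm) if (!is.null(x)) x else
    if (!is.null(opts[[nm]])) opts[[nm]] else TRUE
  use_lsym <- pick(use_lsym, "lsym")
  use_ties <- pick(use_ties, "ties")
  use_special <- pick(use_special, "special")
  np <- length(ATOM_PARAM_NAMES)
  labels <- names(model$atoms)
  nfull <- np * length(labels)
  full_names <- unlist(lapply(labels, function(l) paste(l, ATOM_PARAM_NAMES, sep = ".")))

  tie_leader <- stats::setNames(labels, labels)
  if (use_ties) for (tg in model$ties) for (a in tg) tie_leader[a] <- tg[1]

  offsets <- stats::setNames((seq_along(labels) - 1) * np, labels)
  blk_ranges <- list(xyz = 1:3, U = 4:9, C3 = 10:19, Pv = 20,
                     Plm = 21:44, kappa = 45, kappa_prime = 46)

  Acols <- list(); b <- numeric(nfull)
  free_names <- character(0); free_class <- character(0)
  free_atoms <- list(); pivot_index <- integer(0)
  leader_cols <- list()   # per leader label: free column ids of tied classes

  add_free <- function(col_vals, rows, name, class, atom, pivot_full) {
    v <- numeric(nfull); v[rows] <- col_vals
    Acols[[length(Acols) + 1]] <<- v
    free_names <<- c(free_names, name)
    free_class <<- c(free_class, class)
    free_atoms[[length(free_atoms) + 1]] <<- atom
    pivot_index <<- c(pivot_index, pivot_full)
  }

  blocks_by_atom <- lapply(model$atoms, atom_blocks, model = model,
                           use_lsym = use_lsym, use_special = use_special,
                           tol = tol)

  for (lab in labels) {
    bl <- blocks_by_atom[[lab]]
    off <- offsets[[lab]]
    ## positional / displacement blocks are always per-atom
    for (blkname in c("xyz", "U", "C3")) {
      rows <- off + blk_ranges[[blkname]]
      blk <- bl[[blkname]]
      b[rows] <- blk$b
      for (j in seq_along(blk$piv)) {
        pf <- rows[blk$piv[j]]
        add_free(blk$B[, j], rows, full_names[pf],
                 param_class(ATOM_PARAM_NAMES[blk_ranges[[blkname]][blk$piv[j]]]),
                 lab, pf)
      }
    }
    ## valence blocks: tied classes follow the tie leader
    leader <- tie_leader[[lab]]
    if (leader == lab) {
      cols <- list()
      rows <- off + blk_ranges$Pv
      add_free(1, rows, full_names[rows], "M", lab, rows)
      cols$Pv <- length(Acols)
      blk <- bl$Plm
      rows <- off + blk_ranges$Plm
      plm_cols <- integer(0)
      for (j in seq_along(blk$piv)) {
        pf <- rows[blk$piv[j]]
        add_free(blk$B[, j], rows, full_names[pf],
                 param_class(ATOM_PARAM_NAMES[blk_ranges$Plm[blk$piv[j]]]),
                 lab, pf)
        plm_cols <- c(plm_cols, length(Acols))
      }
      cols$Plm <- plm_cols
      cols$Plm_piv <- blk$piv
      cols$Plm_B <- blk$B
      rows <- off + blk_ranges$kappa
      add_free(1, rows, full_names[rows], "K", lab, rows)
      cols$kappa <- length(Acols)
      rows <- off + blk_ranges$kappa_prime
      add_free(1, rows, full_names[rows], "KP", lab, rows)
      cols$kappa_prime <- length(Acols)
      leader_cols[[lab]] <- cols
    } else {
      ## follower: reuse the leader's free columns
      cols <- leader_cols[[leader]]
      if (is.null(cols))
        stop("tie leader '", leader, "' must precede follower '", lab,
             "' in the atom list")
      fol_blk <- bl$Plm
      if (!identical(dim(fol_blk$B), dim(cols$Plm_B)) ||
          max(abs(fol_blk$B - cols$Plm_B)) > 1e-8)
        stop("tied atoms '", leader, "' and '", lab,
             "' have incompatible multipole constraints")
      Acols[[cols$Pv]][off + blk_ranges$Pv] <- 1
      for (j in seq_along(cols$Plm)) {
        Acols[[cols$Plm[j]]][off + blk_ranges$Plm] <- cols$Plm_B[, j]
      }
      Acols[[cols$kappa]][off + blk_ranges$kappa] <- 1
      Acols[[cols$kappa_prime]][off + blk_ranges$kappa_prime] <- 1
      for (cid in c(cols$Pv, cols$Plm, cols$kappa, cols$kappa_prime))
        free_atoms[[cid]] <- unique(c(free_atoms[[cid]], lab))
    }
  }

  A <- do.call(cbind, Acols)
  colnames(A) <- free_names; rownames(A) <- full_names
  structure(list(A = A, b = b, full_names = full_names,
                 free_names = free_names, free_class = free_class,
                 free_atoms = free_atoms, pivot_index = pivot_index,
                 use_lsym = use_lsym, use_ties = use_ties,
                 use_special = use_special),
            class = "constraint_map")
}

#' @export
print.constraint_map <- function(x, ...) {
  cat(sprintf("constraint map: %d full parameters -> %d free\n",
              length(x$full_names), length(x$free_names)))
  invisible(x)
}

## resolve a selection (classes x atoms, or explicit names) to free columns
resolve_selection <- function(cmap, classes = NULL, atoms = NULL, params = NULL) {
  if (!is.null(params)) {
    bad <- setdiff(params, cmap$free_names)
    if (length(bad))
      stop("selection names parameters that are fixed or forbidden by ",
           "constraints: ", paste(bad, collapse = ", "))
    return(which(cmap$free_names %in% params))
  }
  valid <- c("xyz", "U", "C3", "M", "D", "Q", "O", "H", "K", "KP")
  if (is.null(classes)) stop("selection must give classes or params")
  bad <- setdiff(classes, valid)
  if (length(bad)) stop("unknown parameter classes: ", paste(bad, collapse = ", "),
                        " (valid: ", paste(valid, collapse = ", "), ")")
  sel <- cmap$free_class %in% classes
  if (!is.null(atoms)) {
    hit <- vapply(cmap$free_atoms, function(a) any(a %in% atoms), logical(1))
    sel <- sel & hit
  }
  which(sel)
}

#' Pack model parameters into a free vector
#'
#' @param model a [crystal_model()].
#' @param cmap a [constraint_map()] for the model.
#' @param classes parameter classes to include (`"xyz"`, `"U"`, `"C3"`,
#'   `"M"`, `"D"`, `"Q"`, `"O"`, `"H"`, `"K"`, `"KP"`); NULL with
#'   `params = NULL` selects everything.
#' @param atoms restrict to free parameters driving these atom labels.
#' @param params explicit free-parameter names (overrides classes/atoms);
#'   naming a fixed or forbidden parameter is an error.
#' @return named numeric vector of free-parameter values.
#' @export
pack_parameters <- function(model, cmap, classes = NULL, atoms = NULL,
                            params = NULL) {
  idx <- if (is.null(classes) && is.null(params))
    seq_along(cmap$free_names)
  else resolve_selection(cmap, classes, atoms, params)
  p <- full_params(model)
  stats::setNames(p[cmap$pivot_index[idx]] - cmap$b[cmap$pivot_index[idx]],
                  cmap$free_names[idx])
}

#' Unpack a free vector into a model
#'
#' Values are matched by free-parameter name; unnamed vectors must cover the
#' complete free set in order. All constraint relations (masks, ties,
#' special positions) are applied, so tied atoms receive identical values
#' and forbidden components stay zero.
#'
#' @param f named free-parameter values (subset allowed).
#' @param model a [crystal_model()].
#' @param cmap the [constraint_map()] used to pack.
#' @return updated model.
#' @export
unpack_parameters <- function(f, model, cmap) {
  fall <- pack_parameters(model, cmap)
  if (is.null(names(f))) {
    if (length(f) != length(fall)) stop("unnamed free vector of wrong length")
    fall[] <- f
  } else {
    bad <- setdiff(names(f), names(fall))
    if (length(bad)) stop("unknown free parameters: ", paste(bad, collapse = ", "))
    fall[names(f)] <- f
  }
  p <- as.numeric(cmap$A %*% fall + cmap$b)
  names(p) <- cmap$full_names
  set_full_params(model, p)
}

#' Apply the constraint map to a model in place
#'
#' Projects the model's current parameters onto the constraint manifold
#' (idempotent: applying twice equals applying once).
#' @inheritParams pack_parameters
#' @return conforming model.
#' @export
apply_constraints <- function(model, cmap) {
  unpack_parameters(pack_parameters(model, cmap), model, cmap)
}

#' Site-symmetry constraints of one atom
#'
#' Reports the linear constraints forced on x, y, z, U, C3 and P_lm by the
#' atom's site stabilizer in the given space group (empty for a general
#' position). Constraints are derived by numerical invariance projection of
#' the stabilizer action on each parameter block.
#'
#' @param model a [crystal_model()] containing the atom (cell and local
#'   frame are needed for the P_lm block).
#' @param label atom label.
#' @param tol special-position detection tolerance (fractional units).
#' @return list with `order` (stabilizer size), `fixed` (named values such
#'   as a fixed coordinate), `zero` (parameter names forced to zero) and
#'   `free` (per-block count of remaining free components).
#' @export
site_symmetry_constraints <- function(model, label, tol = 1e-4) {
  atom <- model$atoms[[label]]
  if (is.null(atom)) stop("no atom labelled '", label, "'")
  stab <- site_stabilizer(model$spacegroup, atom$xyz, tol)
  bl <- atom_blocks(model, atom, use_lsym = FALSE, use_special = TRUE, tol = tol)
  fixed <- numeric(0); zero <- character(0); free <- integer(0)
  specs <- list(xyz = c("x", "y", "z"), U = U_NAMES, C3 = C3_NAMES,
                Plm = PLM_NAMES)
  for (bn in names(specs)) {
    blk <- bl[[bn]]
    nms <- specs[[bn]]
    free[bn] <- length(blk$piv)
    dropped <- setdiff(seq_along(nms), blk$piv)
    for (d in dropped) {
      ## component d = sum_j B[d, j] f_j + b[d]; a pure constant is "fixed",
      ## a zero row with zero offset is "zero"
      row <- blk$B[d, , drop = TRUE]
      if (all(abs(row) < 1e-10)) {
        if (abs(blk$b[d]) > 1e-10) fixed[nms[d]] <- blk$b[d]
        else zero <- c(zero, nms[d])
      }
    }
  }
  list(order = length(stab), fixed = fixed, zero = zero, free = free)
}
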