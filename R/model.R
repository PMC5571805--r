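## Crystal model: cell + space group + multipole atoms + constraint info.
## An atom carries the full Hansen-Coppens parameter set: fractional
## coordinates, six CIF-convention U_ij (A^2), ten third-order
## Gram-Charlier coefficients, valence monopole population P_v, 24
## deformation populations P_lm (l = 1..4), kappa and kappa', a local-axis
## definition and a local-symmetry code.

C3_NAMES <- c("C111", "C222", "C333", "C112", "C113",
              "C122", "C123", "C133", "C223", "C233")
## multiplicity of each unique index triple in the contraction C_jkl h_j h_k h_l
C3_MULT <- c(1, 1, 1, 3, 3, 3, 6, 3, 3, 3)
C3_IDX <- list(c(1,1,1), c(2,2,2), c(3,3,3), c(1,1,2), c(1,1,3),
               c(1,2,2), c(1,2,3), c(1,3,3), c(2,2,3), c(2,3,3))
U_NAMES <- c("U11", "U22", "U33", "U12", "U13", "U23")
PLM_NAMES <- multipole_names(4)

#' Construct a multipole atom
#'
#' @param label unique atom label (e.g. `"C1"`).
#' @param element element symbol in the bundled Slater table.
#' @param xyz fractional coordinates, length 3.
#' @param u_iso isotropic starting U (A^2); expanded to a diagonal U tensor
#'   unless `U` is given.
#' @param U six anisotropic components `U11,U22,U33,U12,U13,U23` (CIF, A^2).
#' @param occupancy site occupancy in (0, 1].
#' @param Pv valence monopole population (electrons); defaults to the
#'   neutral-atom valence count.
#' @param Plm named numeric vector of deformation populations (names from
#'   [multipole_names()]); missing entries are 0.
#' @param C3 named numeric vector of third-order Gram-Charlier coefficients
#'   (names `C111`...`C233`); missing entries are 0.
#' @param kappa,kappa_prime radial expansion/contraction scalars (> 0).
#' @param local_axes list with `ref1`, `ref2` atom labels defining the local
#'   frame (z towards `ref1`, x in the plane of `ref2`), or NULL for the
#'   Cartesian frame.
#' @param local_symmetry local point-group code (see
#'   [local_symmetry_ops()]).
#' @param use_c3 logical: is the atom treated anharmonically?
#' @return object of class `mm_atom`.
#' @export
mm_atom <- function(label, element, xyz, u_iso = 0.01, U = NULL,
                    occupancy = 1, Pv = NULL, Plm = NULL, C3 = NULL,
                    kappa = 1, kappa_prime = 1,
                    local_axes = NULL, local_symmetry = "none",
                    use_c3 = FALSE) {
  e <- element_entry(element)
  if (kappa <= 0 || kappa_prime <= 0) stop("kappa and kappa' must be > 0")
  if (occupancy <= 0 || occupancy > 1) stop("occupancy must lie in (0, 1]")
  uu <- stats::setNames(numeric(6), U_NAMES)
  if (is.null(U)) uu[1:3] <- u_iso else {
    if (is.null(names(U))) names(U) <- U_NAMES
    uu[names(U)] <- U
  }
  pl <- stats::setNames(numeric(24), PLM_NAMES)
  if (!is.null(Plm)) pl[names(Plm)] <- Plm
  c3 <- stats::setNames(numeric(10), C3_NAMES)
  if (!is.null(C3)) { c3[names(C3)] <- C3; use_c3 <- use_c3 || any(C3 != 0) }
  ## local-symmetry mask applied at construction: forbidden poles are zero
  mask <- allowed_multipoles(local_symmetry, 4)[PLM_NAMES]
  pl[!mask] <- 0
  structure(list(label = label, element = element, xyz = as.numeric(xyz),
                 occupancy = occupancy, U = uu, C3 = c3,
                 Pv = if (is.null(Pv)) e$valence$nel else Pv,
                 Plm = pl, kappa = kappa, kappa_prime = kappa_prime,
                 local_axes = local_axes, local_symmetry = local_symmetry,
                 use_c3 = use_c3),
            class = "mm_atom")
}

#' Assemble a crystal model
#'
#' @param cell a [unit_cell()].
#' @param spacegroup a [space_group()] (or a symbol string).
#' @param atoms list of [mm_atom()]s (asymmetric unit).
#' @param ties list of character vectors; the atoms named in one vector
#'   share `Pv`, `Plm`, `kappa` and `kappa_prime` (chemical constraints).
#' @return object of class `crystal_model`.
#' @export
crystal_model <- function(cell, spacegroup, atoms, ties = list()) {
  if (is.character(spacegroup)) spacegroup <- space_group(spacegroup)
  labels <- vapply(atoms, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate atom labels")
  names(atoms) <- labels
  for (tg in ties) {
    if (!all(tg %in% labels)) stop("tie group references unknown atoms")
    lsym <- unique(vapply(atoms[tg], `[[`, character(1), "local_symmetry"))
    if (length(lsym) > 1)
      stop("tied atoms must share one local-symmetry code (group: ",
           paste(tg, collapse = ", "), ")")
    els <- unique(vapply(atoms[tg], `[[`, character(1), "element"))
    if (length(els) > 1) stop("tied atoms must share one element")
  }
  structure(list(cell = cell, spacegroup = spacegroup, atoms = atoms,
                 ties = ties),
            class = "crystal_model")
}

#' @export
print.crystal_model <- function(x, ...) {
  cat(sprintf("crystal model: %d atoms, %d symops, %d tie group(s)\n",
              length(x$atoms), length(x$spacegroup$ops), length(x$ties)))
  for (a in x$atoms)
    cat(sprintf("  %-4s %-2s (%.4f %.4f %.4f) lsym=%s%s\n", a$label, a$element,
                a$xyz[1], a$xyz[2], a$xyz[3], a$local_symmetry,
                if (a$use_c3) " +C3" else ""))
  invisible(x)
}

#' Total electron count of the unit-cell contents
#' @param model a [crystal_model()].
#' @return electrons in the cell (sum over symmetry copies, occupancies and
#'   monopole populations).
#' @export
cell_electron_count <- function(model) {
  nsym <- length(model$spacegroup$ops)
  s <- 0
  for (a in model$atoms) {
    e <- element_entry(a$element)
    ncore <- sum(vapply(e$core, `[[`, numeric(1), "nel"))
    s <- s + a$occupancy * (ncore + a$Pv)
  }
  s * nsym
}

## Cartesian local-frame matrix (columns = local x, y, z in Cartesian)
local_frame <- function(model, atom) {
  ax <- atom$local_axes
  if (is.null(ax) || is.null(ax$ref1)) return(diag(3))
  p0 <- as.numeric(frac_to_cart(model$cell, atom$xyz))
  r1 <- model$atoms[[ax$ref1]]
  if (is.null(r1)) stop("local-axis reference '", ax$ref1, "' not found")
  z <- as.numeric(frac_to_cart(model$cell, r1$xyz)) - p0
  z <- z / sqrt(sum(z^2))
  if (!is.null(ax$ref2)) {
    r2 <- model$atoms[[ax$ref2]]
    if (is.null(r2)) stop("local-axis reference '", ax$ref2, "' not found")
    v <- as.numeric(frac_to_cart(model$cell, r2$xyz)) - p0
  } else {
    v <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  }
  x <- v - sum(v * z) * z
  nx <- sqrt(sum(x^2))
  if (nx < 1e-8) stop("local-axis references are collinear for atom ", atom$label)
  x <- x / nx
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  ## right-handed frame with y = z cross x
  cbind(x, y, z)
}

## ---- structured text (YAML) model config round trip ----

#' Write a crystal model to a YAML config file
#' @param model a [crystal_model()].
#' @param path output file.
#' @export
write_model <- function(model, path) {
  atoms <- lapply(model$atoms, function(a) {
    out <- list(label = a$label, element = a$element,
                xyz = as.numeric(a$xyz), occupancy = a$occupancy,
                U = as.list(a$U), kappa = a$kappa, kappa_prime = a$kappa_prime,
                Pv = a$Pv, local_symmetry = a$local_symmetry,
                use_c3 = a$use_c3)
    nz <- a$Plm[a$Plm != 0]
    if (length(nz)) out$Plm <- as.list(nz)
    nz3 <- a$C3[a$C3 != 0]
    if (length(nz3)) out$C3 <- as.list(nz3)
    if (!is.null(a$local_axes)) out$local_axes <- a$local_axes
    out
  })
  cfg <- list(
    cell = list(a = model$cell$a, b = model$cell$b, c = model$cell$c,
                alpha = model$cell$alpha, beta = model$cell$beta,
                gamma = model$cell$gamma),
    symops = vapply(model$spacegroup$ops, symop_to_string, character(1)),
    atoms = unname(atoms),
    ties = lapply(model$ties, as.list)
  )
  yaml::write_yaml(cfg, path, precision = 12)
  invisible(path)
}

#' Read a crystal model from a YAML config file
#' @param path file written by [write_model()] (or hand-authored in the same
#'   layout).
#' @return a [crystal_model()].
#' @export
read_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  cell <- unit_cell(cfg$cell$a, cfg$cell$b, cfg$cell$c,
                    cfg$cell$alpha, cfg$cell$beta, cfg$cell$gamma)
  sg <- space_group(unlist(cfg$symops))
  atoms <- lapply(cfg$atoms, function(a) {
    mm_atom(a$label, a$element, unlist(a$xyz),
            U = unlist(a$U), occupancy = a$occupancy,
            Pv = a$Pv, Plm = if (!is.null(a$Plm)) unlist(a$Plm),
            C3 = if (!is.null(a$C3)) unlist(a$C3),
            kappa = a$kappa, kappa_prime = a$kappa_prime,
            local_axes = a$local_axes, local_symmetry = a$local_symmetry,
            use_c3 = isTRUE(a$use_c3))
  })
  crystal_model(cell, sg, atoms,
                ties = lapply(cfg$ties, function(x) unlist(x)))
}
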