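## Symmetry-operator algebra. Operators are stored as integer 3x3 rotation
## matrices plus rational translation vectors, parsed from "x,y,z"-style
## triplet strings (the only symmetry interchange format supported).

parse_symop_term <- function(term, line) {
  term <- gsub("[[:space:]]", "", term)
  if (!nzchar(term)) stop("empty symmetry-operator component in '", line, "'")
  rot <- c(x = 0, y = 0, z = 0)
  tr <- 0
  # tokenize into signed pieces
  pieces <- regmatches(term, gregexpr("[+-]?[^+-]+", term))[[1]]
  for (p in pieces) {
    sign <- if (startsWith(p, "-")) -1 else 1
    body <- sub("^[+-]", "", p)
    if (grepl("^[xyz]$", body)) {
      rot[body] <- rot[body] + sign
    } else if (grepl("^[0-9]+/[0-9]+$", body)) {
      num <- as.numeric(strsplit(body, "/")[[1]])
      tr <- tr + sign * num[1] / num[2]
    } else if (grepl("^[0-9.]+$", body)) {
      tr <- tr + sign * as.numeric(body)
    } else {
      stop("cannot parse symmetry-operator component '", p, "' in '", line, "'")
    }
  }
  list(rot = rot, tr = tr)
}

#' Parse a symmetry operator string
#'
#' @param s a triplet string such as `"-x+1/2, y, z+1/2"`.
#' @return list with integer 3x3 `R` and length-3 translation `t` in \[0,1).
#' @export
parse_symop <- function(s) {
  parts <- strsplit(s, ",")[[1]]
  if (length(parts) != 3) stop("symmetry operator '", s, "' does not have three components")
  R <- matrix(0L, 3, 3)
  tvec <- numeric(3)
  for (i in 1:3) {
    pt <- parse_symop_term(parts[i], s)
    R[i, ] <- as.integer(pt$rot)
    tvec[i] <- pt$tr %% 1
  }
  list(R = R, t = tvec)
}

symop_to_string <- function(op) {
  ax <- c("x", "y", "z")
  comp <- character(3)
  for (i in 1:3) {
    s <- ""
    for (j in 1:3) {
      r <- op$R[i, j]
      if (r != 0) {
        sgn <- if (r < 0) "-" else if (nzchar(s)) "+" else ""
        mult <- if (abs(r) == 1) "" else as.character(abs(r))
        s <- paste0(s, sgn, mult, ax[j])
      }
    }
    tv <- op$t[i] %% 1
    if (abs(tv) > 1e-9) {
      fr <- rational_string(tv)
      s <- paste0(s, "+", fr)
    }
    comp[i] <- s
  }
  paste(comp, collapse = ",")
}

rational_string <- function(x, max_den = 12) {
  for (d in 1:max_den) {
    n <- round(x * d)
    if (abs(x - n / d) < 1e-9) return(paste0(n, "/", d))
  }
  format(x)
}

#' Space group from symmetry operator strings
#'
#' Builds a space group from generator strings, closing the set under
#' composition modulo lattice translations. Verifies the identity is present
#' and detects centrosymmetry (an operator with rotation -I).
#'
#' @param symops character vector of `"x,y,z"`-style strings, or a known
#'   symbol from [spacegroup_table()] (`"P1"`, `"P-1"`, `"Pm"`, `"P21/c"`,
#'   `"Pnma"`).
#' @param centering lattice centering code (only `"P"` supported).
#' @return object of class `space_group` with fields `ops` (list of R, t),
#'   `centrosymmetric`, `symbol`.
#' @export
space_group <- function(symops, centering = "P") {
  if (length(symops) == 1 && !grepl(",", symops)) {
    sym <- symops
    symops <- spacegroup_table()[[sym]]
    if (is.null(symops)) stop("unknown space-group symbol '", sym, "'; known: ",
                              paste(names(spacegroup_table()), collapse = ", "))
  } else sym <- NA_character_
  if (centering != "P") stop("only primitive (P) centering is supported")
  ops <- lapply(symops, parse_symop)
  ops <- close_group(ops)
  centro <- any(vapply(ops, function(o) all(o$R == -diag(3)), logical(1)))
  structure(list(ops = ops, centrosymmetric = centro,
                 centering = centering, symbol = sym),
            class = "space_group")
}

op_key <- function(op) paste(c(op$R, round(op$t %% 1, 6)), collapse = ",")

compose_op <- function(a, b) {
  ## (Ra,ta) o (Rb,tb): x -> Ra(Rb x + tb) + ta
  list(R = a$R %*% b$R, t = (as.numeric(a$R %*% b$t) + a$t) %% 1)
}

close_group <- function(ops, max_order = 192) {
  ident <- list(R = diag(3L), t = numeric(3))
  seen <- new.env(parent = emptyenv())
  out <- list(ident)
  assign(op_key(ident), TRUE, envir = seen)
  queue <- ops
  while (length(queue)) {
    op <- queue[[1]]; queue <- queue[-1]
    op$t <- op$t %% 1
    k <- op_key(op)
    if (!exists(k, envir = seen)) {
      assign(k, TRUE, envir = seen)
      out <- c(out, list(op))
      if (length(out) > max_order) stop("symmetry operator set does not close")
      for (o in out) {
        queue <- c(queue, list(compose_op(op, o)), list(compose_op(o, op)))
      }
    }
  }
  out
}

#' Built-in space-group generator strings
#'
#' A small table of the settings used by the toy scenarios. Arbitrary groups
#' can be supplied directly as operator strings.
#' @return named list of character vectors.
#' @export
spacegroup_table <- function() {
  list(
    "P1"    = c("x,y,z"),
    "P-1"   = c("x,y,z", "-x,-y,-z"),
    "Pm"    = c("x,y,z", "x,-y,z"),
    "P21/c" = c("x,y,z", "-x,y+1/2,-z+1/2", "-x,-y,-z", "x,-y+1/2,z+1/2"),
    "Pnma"  = c("x,y,z", "-x+1/2,-y,z+1/2", "-x,y+1/2,-z",
                "x+1/2,-y+1/2,-z+1/2", "-x,-y,-z", "x+1/2,y,-z+1/2",
                "x,-y+1/2,z", "-x+1/2,y+1/2,z+1/2")
  )
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf("space group%s: %d operators, %scentrosymmetric\n",
              if (!is.na(x$symbol)) paste0(" ", x$symbol) else "",
              length(x$ops), if (x$centrosymmetric) "" else "non-"))
  invisible(x)
}

## Laue rotations: unique rotation parts augmented with the inversion
## (Friedel). Used for canonical reflection keys.
laue_rotations <- function(sg) {
  Rs <- lapply(sg$ops, `[[`, "R")
  Rs <- c(Rs, lapply(Rs, function(R) -R))
  keys <- vapply(Rs, function(R) paste(R, collapse = ","), character(1))
  Rs[!duplicated(keys)]
}

## rotations only (no Friedel) -- for acentric unique sets
point_rotations <- function(sg) {
  Rs <- lapply(sg$ops, `[[`, "R")
  keys <- vapply(Rs, function(R) paste(R, collapse = ","), character(1))
  Rs[!duplicated(keys)]
}

## site stabilizer: ops with R x0 + t = x0 (mod 1) within tol
site_stabilizer <- function(sg, x0, tol = 1e-4) {
  keep <- vapply(sg$ops, function(op) {
    d <- (as.numeric(op$R %*% x0) + op$t - x0) %% 1
    d <- pmin(d, 1 - d)
    all(abs(d) < tol)
  }, logical(1))
  sg$ops[keep]
}

canonical_hkl <- function(hkl, rotations) {
  ## lexicographically maximal image over the orbit {h R}: reflections
  ## transform as row vectors, h.(Rx) = (hR).x
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  best <- h %*% rotations[[1]]
  if (length(rotations) > 1) {
    for (R in rotations[-1]) {
      cand <- h %*% R
      ## lexicographic comparison cand > best
      gt <- (cand[, 1] > best[, 1]) |
        (cand[, 1] == best[, 1] & cand[, 2] > best[, 2]) |
        (cand[, 1] == best[, 1] & cand[, 2] == best[, 2] & cand[, 3] > best[, 3])
      if (any(gt)) best[gt, ] <- cand[gt, , drop = FALSE]
    }
  }
  best
}
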