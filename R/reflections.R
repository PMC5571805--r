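## Reflection container. A reflection_set wraps a data.frame with columns
## h, k, l, Fo2, sigma, stol, cv_set plus the associated cell and a merged
## flag. Data stay on F^2 as read (SHELX HKLF 4 convention); conversion to
## |F| happens only in the R-factor layer.

#' Construct a reflection set
#'
#' @param df data.frame with columns `h, k, l, Fo2, sigma` (and optionally
#'   `cv_set`).
#' @param cell a [unit_cell()] used to compute `stol`.
#' @param merged logical: has the set been merged to unique reflections?
#' @return object of class `reflection_set`.
#' @export
reflection_set <- function(df, cell, merged = FALSE) {
  need <- c("h", "k", "l", "Fo2", "sigma")
  if (!all(need %in% names(df))) stop("missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  if (any(df$h == 0 & df$k == 0 & df$l == 0)) stop("(0,0,0) is not a reflection")
  if (any(df$sigma <= 0)) warning(sum(df$sigma <= 0), " reflections with sigma <= 0 flagged")
  df$stol <- stol(cell, as.matrix(df[, c("h", "k", "l")]))
  if (is.null(df$cv_set)) df$cv_set <- rep(NA_integer_, nrow(df))
  structure(list(data = df, cell = cell, merged = merged),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("reflection set: %d reflections, stol %.3f-%.3f 1/A%s\n",
              nrow(x$data), min(x$data$stol), max(x$data$stol),
              if (x$merged) ", merged" else ""))
  invisible(x)
}

#' Number of reflections
#' @param set a [reflection_set()].
#' @return integer count.
#' @export
n_reflections <- function(set) nrow(set$data)

#' Read a SHELX HKLF 4 file
#'
#' Fixed-format records `3I4, 2F8.2` (h k l Fo^2 sigma); a `0 0 0` record
#' terminates the file. Malformed records raise an error naming the line.
#'
#' @param path file path.
#' @param cell a [unit_cell()].
#' @return a [reflection_set()] (unmerged).
#' @export
read_shelx_hkl <- function(path, cell) {
  lines <- readLines(path)
  rows <- vector("list", length(lines))
  nrec <- 0
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (nchar(ln) < 28) ln <- formatC(ln, width = -28)
    h <- suppressWarnings(as.integer(substr(ln, 1, 4)))
    k <- suppressWarnings(as.integer(substr(ln, 5, 8)))
    l <- suppressWarnings(as.integer(substr(ln, 9, 12)))
    fo <- suppressWarnings(as.numeric(substr(ln, 13, 20)))
    sg <- suppressWarnings(as.numeric(substr(ln, 21, 28)))
    if (any(is.na(c(h, k, l))))
      stop("malformed HKL record at line ", i, ": '", lines[i], "'")
    if (h == 0 && k == 0 && l == 0) break
    if (any(is.na(c(fo, sg))))
      stop("malformed HKL record at line ", i, ": '", lines[i], "'")
    nrec <- nrec + 1
    rows[[nrec]] <- c(h, k, l, fo, sg)
  }
  if (nrec == 0) {
    df <- data.frame(h = integer(0), k = integer(0), l = integer(0),
                     Fo2 = numeric(0), sigma = numeric(0))
  } else {
    m <- do.call(rbind, rows[seq_len(nrec)])
    df <- data.frame(h = as.integer(m[, 1]), k = as.integer(m[, 2]),
                     l = as.integer(m[, 3]), Fo2 = m[, 4], sigma = m[, 5])
  }
  if (nrow(df)) reflection_set(df, cell) else {
    df$stol <- numeric(0); df$cv_set <- integer(0)
    structure(list(data = df, cell = cell, merged = FALSE),
              class = "reflection_set")
  }
}

#' Write a SHELX HKLF 4 file
#'
#' @param set a [reflection_set()].
#' @param path output path.
#' @export
write_shelx_hkl <- function(set, path) {
  d <- set$data
  if (nrow(d) && (max(abs(d$Fo2)) >= 1e5 || max(d$sigma) >= 1e5))
    stop("F^2 values too large for fixed-width HKLF 4 records (8-column ",
         "F8.2 fields); rescale first")
  if (nrow(d) && any(d$sigma < 0.005))
    stop("sigma values would round to zero in fixed-width HKLF 4 records; ",
         "rescale the data first (the overall scale is arbitrary)")
  recs <- sprintf("%4d%4d%4d%8.2f%8.2f", d$h, d$k, d$l, d$Fo2, d$sigma)
  writeLines(c(recs, sprintf("%4d%4d%4d%8.2f%8.2f", 0L, 0L, 0L, 0, 0)), path)
  invisible(path)
}

#' Export a reflection set as CSV
#'
#' Interchange table with stol, cv_set and optional Fo/Fc columns.
#' @param set a [reflection_set()].
#' @param path output path.
#' @param Fc optional complex or numeric model structure factors (|Fc| is
#'   written).
#' @export
write_refl_csv <- function(set, path, Fc = NULL) {
  d <- set$data
  d$Fo <- sqrt(pmax(d$Fo2, 0))
  if (!is.null(Fc)) d$Fc <- Mod(Fc)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Canonical Friedel/Laue key for reflections
#'
#' Maps h and -h (and all Laue-group images) to one canonical index triple,
#' the lexicographically maximal orbit member. Friedel pairing is applied
#' unconditionally, as the pairing is about statistical dependence, not
#' crystal symmetry.
#'
#' @param hkl n x 3 matrix (or length-3 vector) of indices.
#' @param spacegroup a [space_group()].
#' @return character vector of keys (`"h,k,l"`).
#' @export
friedel_key <- function(hkl, spacegroup) {
  can <- canonical_hkl(hkl, laue_rotations(spacegroup))
  paste(can[, 1], can[, 2], can[, 3], sep = ",")
}

#' Split a reflection set at a resolution cut
#'
#' @param set a [reflection_set()].
#' @param cut sin(theta)/lambda cut in 1/angstrom (default 0.5).
#' @return list with `low` (stol <= cut) and `high` (stol > cut)
#'   reflection sets.
#' @export
split_by_resolution <- function(set, cut = 0.5) {
  lo <- set$data$stol <= cut
  list(low = subset_refl(set, lo), high = subset_refl(set, !lo))
}

subset_refl <- function(set, idx) {
  structure(list(data = set$data[idx, , drop = FALSE], cell = set$cell,
                 merged = set$merged), class = "reflection_set")
}

#' Merge symmetry-equivalent reflections
#'
#' Groups reflections by canonical key (Laue group; Friedel mates are
#' merged only when `friedel = TRUE`) and replaces each group by its
#' inverse-variance weighted mean F^2 with sigma = sqrt(1/sum(w)).
#' R_int is attached as an attribute, reported but not used downstream.
#'
#' @param set a [reflection_set()].
#' @param spacegroup a [space_group()].
#' @param friedel merge Friedel mates too (TRUE for centrosymmetric work).
#' @return merged [reflection_set()] with attribute `"R_int"`.
#' @export
merge_reflections <- function(set, spacegroup, friedel = TRUE) {
  d <- set$data
  rots <- if (friedel) laue_rotations(spacegroup) else point_rotations(spacegroup)
  can <- canonical_hkl(as.matrix(d[, c("h", "k", "l")]), rots)
  key <- paste(can[, 1], can[, 2], can[, 3], sep = ",")
  w <- 1 / d$sigma^2
  sw <- rowsum(w, key); swf <- rowsum(w * d$Fo2, key)
  fbar <- swf / sw
  ix <- match(rownames(sw), key)            # one representative per group
  hklu <- can[ix, , drop = FALSE]
  ## R_int = sum |F2 - <F2>| / sum F2 over multiply-measured groups
  fbar_each <- fbar[match(key, rownames(sw))]
  counts <- rowsum(rep(1, length(key)), key)
  multi <- key %in% rownames(counts)[counts > 1]
  rint <- if (any(multi))
    sum(abs(d$Fo2[multi] - fbar_each[multi])) / sum(abs(d$Fo2[multi])) else NA_real_
  out <- data.frame(h = as.integer(hklu[, 1]), k = as.integer(hklu[, 2]),
                    l = as.integer(hklu[, 3]),
                    Fo2 = as.numeric(fbar), sigma = as.numeric(sqrt(1 / sw)))
  res <- reflection_set(out, set$cell, merged = TRUE)
  attr(res, "R_int") <- rint
  res
}
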