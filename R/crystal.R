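# Pseudo-crystal model: unit cell, P1 symmetry, reciprocal lattice and
# reflection-set generation by resolution shell.

#' Unit cell
#'
#' Direct-lattice cell in angstrom/degrees with its reciprocal matrix
#' \eqn{B} (so that the reciprocal vector of Miller triple h is \eqn{q = Bh},
#' in 1/angstrom).  Only P1 symmetry (identity operation) is supported by the
#' package; the pseudo-crystal of the study is a 10 angstrom cube.
#'
#' @param a,b,c cell lengths, angstrom.
#' @param alpha,beta,gamma cell angles, degrees.
#' @return Object of class `xcw_cell` with fields `lengths`, `angles`,
#'   `A` (direct-lattice column matrix, angstrom) and `B` (reciprocal matrix,
#'   1/angstrom).
#' @export
unit_cell <- function(a = 10, b = a, c = a, alpha = 90, beta = 90, gamma = 90) {
  if (any(c(a, b, c) <= 0)) stop("cell lengths must be positive")
  ar <- alpha * pi / 180; br <- beta * pi / 180; gr <- gamma * pi / 180
  # direct lattice vectors as columns, standard crystallographic frame
  av <- c(a, 0, 0)
  bv <- c(b * cos(gr), b * sin(gr), 0)
  cx <- c * cos(br)
  cy <- c * (cos(ar) - cos(br) * cos(gr)) / sin(gr)
  cz2 <- c^2 - cx^2 - cy^2
  if (cz2 <= 0) stop("degenerate cell: zero or negative volume")
  cv <- c(cx, cy, sqrt(cz2))
  A <- cbind(av, bv, cv)
  vol <- det(A)
  if (vol <= 1e-10) stop("degenerate cell: zero volume")
  B <- t(solve(A))          # inverse transpose: q = B %*% h
  structure(list(lengths = c(a = a, b = b, c = c),
                 angles = c(alpha = alpha, beta = beta, gamma = gamma),
                 A = A, B = B, volume = vol),
            class = "xcw_cell")
}

#' @export
print.xcw_cell <- function(x, ...) {
  cat(sprintf("<unit cell a=%.3f b=%.3f c=%.3f A, alpha=%.2f beta=%.2f gamma=%.2f, V=%.2f A^3>\n",
              x$lengths[1], x$lengths[2], x$lengths[3],
              x$angles[1], x$angles[2], x$angles[3], x$volume))
  invisible(x)
}

#' Reciprocal-lattice matrix of a cell
#' @param cell an [unit_cell()].
#' @return 3x3 matrix B (1/angstrom) with q = B h.
#' @export
build_reciprocal_matrix <- function(cell) cell$B

#' Resolution of a reflection
#'
#' \eqn{s = \sin\theta/\lambda = |Bh|/2} in 1/angstrom.
#'
#' @param hkl integer triple or nx3 matrix of Miller indices.
#' @param cell an [unit_cell()].
#' @return Numeric vector of resolutions.
#' @export
resolution_of <- function(hkl, cell) {
  h <- matrix(as.numeric(hkl), ncol = 3)
  q <- h %*% t(cell$B)
  sqrt(rowSums(q^2)) / 2
}

#' Generate a reflection set up to a resolution cutoff
#'
#' Enumerates all integer Miller triples (origin excluded) with
#' \eqn{s \le s_{max}}.  Under the `unique-hemisphere` Friedel policy only the
#' lexicographically positive member of each Friedel pair (h, -h) is kept:
#' the electron density is real, so |F(h)| = |F(-h)| and a hemisphere carries
#' the full information content.  Reflections are ordered lexicographically
#' by (h, k, l).
#'
#' @param cell an [unit_cell()].
#' @param s_max resolution cutoff sin(theta)/lambda, 1/angstrom.
#' @param friedel `"unique-hemisphere"` (default) or `"full-sphere"`.
#' @return Object of class `xcw_reflections`: data frame `hkl` (h, k, l, s,
#'   F_obs = NA, sigma = 1) plus the cell and policy metadata.
#' @export
generate_reflection_set <- function(cell, s_max,
                                    friedel = c("unique-hemisphere", "full-sphere")) {
  friedel <- match.arg(friedel)
  if (s_max <= 0) stop("s_max must be positive")
  # bounding box in h-space: |h_i| <= 2 s_max * max direct axis length
  hmax <- ceiling(2 * s_max * max(svd(cell$A)$d)) + 1L
  grid <- expand.grid(l = -hmax:hmax, k = -hmax:hmax, h = -hmax:hmax)
  H <- as.matrix(grid[, c("h", "k", "l")])
  s <- resolution_of(H, cell)
  keep <- s <= s_max + 1e-12 & !(H[, 1] == 0 & H[, 2] == 0 & H[, 3] == 0)
  H <- H[keep, , drop = FALSE]
  s <- s[keep]
  if (friedel == "unique-hemisphere" && nrow(H) > 0) {
    pos <- H[, 1] > 0 | (H[, 1] == 0 & H[, 2] > 0) |
      (H[, 1] == 0 & H[, 2] == 0 & H[, 3] > 0)
    H <- H[pos, , drop = FALSE]
    s <- s[pos]
  }
  ord <- order(H[, 1], H[, 2], H[, 3])
  H <- H[ord, , drop = FALSE]
  s <- s[ord]
  reflection_set(cell, H, s = s, F_obs = rep(NA_real_, nrow(H)),
                 sigma = rep(1, nrow(H)), s_max = s_max, friedel = friedel)
}

reflection_set <- function(cell, H, s = NULL, F_obs, sigma, s_max = NULL, friedel) {
  H <- matrix(as.integer(round(H)), ncol = 3,
              dimnames = list(NULL, c("h", "k", "l")))
  if (any(H[, 1] == 0 & H[, 2] == 0 & H[, 3] == 0)) {
    stop("the origin reflection (0,0,0) may not appear in a constraint set")
  }
  if (anyDuplicated(H)) stop("duplicate Miller indices in reflection set")
  if (any(sigma <= 0, na.rm = TRUE)) stop("all sigma must be positive")
  if (is.null(s)) s <- resolution_of(H, cell)
  if (is.null(s_max)) s_max <- max(s)
  structure(list(cell = cell,
                 hkl = data.frame(H, s = s, F_obs = as.numeric(F_obs),
                                  sigma = as.numeric(sigma)),
                 s_max = s_max, friedel = friedel),
            class = "xcw_reflections")
}

#' @export
print.xcw_reflections <- function(x, ...) {
  cat(sprintf("<reflection set: %d reflections, s_max = %.3f 1/A, %s>\n",
              nrow(x$hkl), x$s_max, x$friedel))
  invisible(x)
}

#' Number of reflections in a set
#' @param refs an `xcw_reflections` object.
#' @return Integer count N_r.
#' @export
n_reflections <- function(refs) nrow(refs$hkl)

#' Read / write plain-text hkl reflection files
#'
#' Whitespace-separated columns `h k l F sigma`; lines starting with `#` are
#' comments.  The origin reflection and non-positive sigmas are rejected.
#'
#' @param path file path.
#' @param cell the [unit_cell()] the indices refer to.
#' @param friedel Friedel policy tag to attach on read.
#' @return `read_hkl`: an `xcw_reflections` object.
#' @export
read_hkl <- function(path, cell, friedel = "unique-hemisphere") {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(parts) != 5)
  if (length(bad)) {
    stop("malformed hkl line ", keep[bad[1]], ": expected 5 columns, got ",
         length(parts[[bad[1]]]))
  }
  m <- do.call(rbind, lapply(parts, as.numeric))
  if (anyNA(m)) {
    row <- which(apply(is.na(m), 1, any))[1]
    stop("malformed hkl line ", keep[row], ": non-numeric field")
  }
  reflection_set(cell, m[, 1:3, drop = FALSE], F_obs = m[, 4], sigma = m[, 5],
                 friedel = friedel)
}

#' @rdname read_hkl
#' @param refs an `xcw_reflections` object to write.
#' @export
write_hkl <- function(refs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hkl reflection file: h k l F sigma (cell a=%.4f b=%.4f c=%.4f A)",
                     refs$cell$lengths[1], refs$cell$lengths[2], refs$cell$lengths[3]), con)
  with(refs$hkl, writeLines(sprintf("%4d %4d %4d %15.6g %10.6g", h, k, l, F_obs, sigma), con))
  invisible(path)
}
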