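# Attachment/detachment decomposition of a density-matrix difference, and
# Gaussian cube file I/O for rendering the resulting fields.

#' Attachment/detachment decomposition
#'
#' Splits the difference between a reference (here: unconstrained RHF) and a
#' correlated or constrained one-particle density into its negative
#' (detachment D) and positive (attachment A) eigencomponents.  The
#' difference is symmetrically (Lowdin) orthogonalized with S^{1/2} before
#' the eigendecomposition, so A and D are positive semidefinite in the
#' orthonormal basis and A - D reproduces the difference exactly.  The
#' promoted-electron number p is the common trace of A and D (against S).
#'
#' @param P_ref,P_corr total AO density matrices with equal electron count,
#'   or `xcw_density` objects on the same basis.
#' @param S AO overlap matrix (taken from the densities when omitted).
#' @return Object of class `xcw_attach_detach`: matrices `A`, `D` (AO
#'   basis), `p` (promoted electrons), and the traces `tr_AS`, `tr_DS`.
#' @export
attach_detach_decomposition <- function(P_ref, P_corr, S = NULL) {
  if (inherits(P_ref, "xcw_density")) {
    if (is.null(S)) S <- P_ref$ints$S
    P_ref <- P_ref$P
  }
  if (inherits(P_corr, "xcw_density")) P_corr <- P_corr$P
  if (is.null(S)) stop("need the AO overlap matrix S")
  tr_ref <- sum(P_ref * S); tr_corr <- sum(P_corr * S)
  if (abs(tr_ref - tr_corr) > 1e-6) {
    stop("electron-count mismatch between the two densities: ",
         format(tr_ref), " vs ", format(tr_corr))
  }
  es <- eigen(S, symmetric = TRUE)
  S12 <- es$vectors %*% (sqrt(es$values) * t(es$vectors))
  Sm12 <- es$vectors %*% ((1 / sqrt(es$values)) * t(es$vectors))
  Dlt <- S12 %*% (P_corr - P_ref) %*% S12
  ed <- eigen((Dlt + t(Dlt)) / 2, symmetric = TRUE)
  pos <- pmax(ed$values, 0)
  neg <- pmax(-ed$values, 0)
  Ao <- ed$vectors %*% (pos * t(ed$vectors))
  Do <- ed$vectors %*% (neg * t(ed$vectors))
  A <- Sm12 %*% Ao %*% Sm12
  D <- Sm12 %*% Do %*% Sm12
  structure(list(A = A, D = D, p = sum(pos),
                 tr_AS = sum(A * S), tr_DS = sum(D * S),
                 eigenvalues = ed$values),
            class = "xcw_attach_detach")
}

#' @export
print.xcw_attach_detach <- function(x, ...) {
  cat(sprintf("<attachment/detachment: p = %.6f electrons promoted>\n", x$p))
  invisible(x)
}

#' Write / read Gaussian cube files
#'
#' Standard cube grammar: two comment lines, atom count + origin, three
#' axis records (counts + voxel vectors, bohr), atom records (Z, charge,
#' position), then values with z fastest.  Fields in this package store x
#' fastest; the writer/reader permute accordingly.
#'
#' @param field an `xcw_field`.
#' @param mol an [molecule()] sharing the field's coordinate frame.
#' @param path output path.
#' @param comment first header line.
#' @return `write_cube`: the path, invisibly.  `read_cube`: an `xcw_field`.
#' @export
write_cube <- function(field, mol, path, comment = "electron density") {
  g <- field$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(comment, "cube written by xcwfit (bohr)"), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", length(mol$Z),
                     g$origin[1], g$origin[2], g$origin[3]), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", g$npts[1], g$spacing[1], 0, 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", g$npts[2], 0, g$spacing[2], 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", g$npts[3], 0, 0, g$spacing[3]), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", mol$Z, as.numeric(mol$Z),
                     mol$xyz[, 1], mol$xyz[, 2], mol$xyz[, 3]), con)
  arr <- array(field$values, g$npts)      # x fastest in memory
  vals <- as.numeric(aperm(arr, c(3, 2, 1)))  # cube wants z fastest
  # 6 values per line, %13.5E
  nfull <- length(vals) %/% 6L
  if (nfull > 0) {
    m <- matrix(vals[seq_len(nfull * 6L)], ncol = 6, byrow = TRUE)
    writeLines(apply(m, 1, function(r) paste(sprintf("%13.5E", r), collapse = "")), con)
  }
  rest <- vals[-seq_len(nfull * 6L)]
  if (length(rest)) writeLines(paste(sprintf("%13.5E", rest), collapse = ""), con)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[3:6]), "\\s+")
  natom <- as.integer(hdr[[1]][1])
  origin <- as.numeric(hdr[[1]][2:4])
  npts <- vapply(hdr[2:4], function(h) as.integer(h[1]), 0L)
  spacing <- c(as.numeric(hdr[[2]][2]), as.numeric(hdr[[3]][3]), as.numeric(hdr[[4]][4]))
  at <- strsplit(trimws(lines[7:(6 + natom)]), "\\s+")
  Z <- vapply(at, function(a) as.integer(a[1]), 0L)
  xyz <- t(vapply(at, function(a) as.numeric(a[3:5]), numeric(3)))
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:(6 + natom))]), "\\s+")))
  if (length(vals) != prod(npts)) {
    stop("cube data length ", length(vals), " does not match header voxel count ", prod(npts))
  }
  arr <- array(vals, rev(npts))           # file is z fastest
  vals <- as.numeric(aperm(arr, c(3, 2, 1)))
  # cube files carry no net charge; keep the bare geometry without the
  # closed-shell validation of molecule()
  mol <- structure(list(Z = Z, xyz = xyz, charge = NA_integer_,
                        multiplicity = NA_integer_, nelec = NA_integer_,
                        comment = lines[1]),
                   class = "xcw_molecule")
  g <- grid_spec(origin, spacing, npts)
  structure(list(grid = g, values = vals, molecule = mol,
                 nelec_grid = sum(vals) * g$voxel, method = NA),
            class = "xcw_field")
}
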