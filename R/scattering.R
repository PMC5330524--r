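# Structure factors: analytic Fourier transforms of Gaussian AO pair
# densities on the reciprocal lattice of the pseudo-crystal, contraction
# with one-particle density matrices, and a closed-form toy model.
#
# Phase convention: F(h) = integral rho(r) exp(+2 pi i (Bh).r) dr.  The
# molecule is placed at the geometric center of the cell; this affects
# phases only, never amplitudes.

#' Fourier-transform integrals of AO pair densities
#'
#' For every reflection h computes the complex nbf x nbf matrix
#' \deqn{I_{h,\mu\nu} = \int \chi_\mu(r)\chi_\nu(r) e^{2\pi i (Bh)\cdot r} dr,}
#' analytically via the Hermite-Gaussian expansion of the pair density (no
#' grids involved).  I_0 is the AO overlap matrix; I_{-h} is the complex
#' conjugate of I_h.
#'
#' @param basis an `xcw_basis` (or molecule + basis name via
#'   [build_basis()]).
#' @param refs an `xcw_reflections` set carrying the cell.
#' @return Object of class `xcw_ftblocks`: complex matrix `M` (nbf^2 x N_r,
#'   column h = vec(I_h)) plus reflection/cell metadata.
#' @export
ft_ao_pair_integrals <- function(basis, refs) {
  if (!inherits(basis, "xcw_basis")) stop("basis must be an xcw_basis object")
  if (!inherits(refs, "xcw_reflections")) stop("refs must be an xcw_reflections object")
  H <- as.matrix(refs$hkl[, c("h", "k", "l")])
  q_ang <- H %*% t(refs$cell$B)                 # 1/angstrom
  q_bohr <- q_ang / BOHR_PER_ANGSTROM           # 1/bohr, consistent with centers
  # place the molecule at the geometric center of the cell (phases only):
  # translate the shell centers before transforming
  cen_mol <- colMeans(basis$molecule$xyz)
  cen_cell <- angstrom_to_bohr(as.numeric(refs$cell$A %*% c(0.5, 0.5, 0.5)))
  shift <- cen_cell - cen_mol
  shells <- lapply(basis$shells, function(s) { s$center <- s$center + shift; s })
  M <- cpp_ft_blocks(shells, q_bohr)
  n <- basis$nbf
  lt <- lower.tri(diag(n), diag = TRUE)
  lowidx <- which(lt)
  wpack <- rep(2, length(lowidx))
  wpack[diag(n)[lt] == 1] <- 1                  # diagonal entries
  structure(list(M = M, refs = refs, nbf = n, lowidx = lowidx, wpack = wpack,
                 basis_name = basis$name, shift = shift),
            class = "xcw_ftblocks")
}

# unpack the stored lower triangle of reflection k into the full complex
# symmetric nbf x nbf matrix I_h
ftblock_matrix <- function(blocks, k) {
  n <- blocks$nbf
  M <- matrix(0 + 0i, n, n)
  M[blocks$lowidx] <- blocks$M[, k]
  M <- M + t(M)
  diag(M) <- diag(M) / 2
  M
}

#' @export
print.xcw_ftblocks <- function(x, ...) {
  cat(sprintf("<FT blocks: %d reflections x %d^2 AO pairs (%s)>\n",
              ncol(x$M), x$nbf, x$basis_name))
  invisible(x)
}

#' Structure factors from a density matrix
#'
#' Contracts a total one-particle density matrix with the FT integral
#' blocks: \eqn{F_h = \sum_{\mu\nu} P_{\mu\nu} I_{h,\mu\nu}} (P1 cell, one
#' symmetry operation).
#'
#' @param P a total AO density matrix, or an `xcw_density`.
#' @param blocks an [ft_ao_pair_integrals()] result.
#' @return Complex vector of structure factors, one per reflection.
#' @export
structure_factors_from_density <- function(P, blocks) {
  if (inherits(P, "xcw_density")) P <- P$P
  n <- blocks$nbf
  if (!is.matrix(P) || nrow(P) != n || ncol(P) != n) {
    stop("density matrix dimension does not match FT blocks (", n, " AOs)")
  }
  # blocks hold the lower triangle of the symmetric I_h: off-diagonal AO
  # pairs enter the contraction twice
  as.vector(crossprod(blocks$M, P[blocks$lowidx] * blocks$wpack))
}

#' Amplitudes with scale factor
#'
#' @param F complex structure factors.
#' @param eta positive scale factor (1 for theoretical constraints).
#' @return Nonnegative amplitudes |eta F|.
#' @export
amplitude_set <- function(F, eta = 1) {
  if (eta <= 0) stop("eta must be positive")
  eta * Mod(F)
}

#' Toy Gaussian density model
#'
#' A sum of normalized isotropic Gaussians (weight = electrons each) whose
#' structure factor has the closed form
#' \eqn{F(q) = \sum_j w_j e^{2\pi i q\cdot c_j} e^{-\pi^2 |q|^2/\alpha_j}}.
#' Used as an independent cross-check of the analytic AO machinery.
#'
#' @param centers n x 3 matrix of positions, bohr.
#' @param exponents Gaussian exponents, 1/bohr^2.
#' @param weights electrons per Gaussian (nonnegative).
#' @return Object of class `xcw_toygauss`.
#' @export
toy_gaussian_model <- function(centers, exponents, weights) {
  centers <- matrix(centers, ncol = 3)
  if (any(exponents <= 0)) stop("Gaussian exponents must be positive")
  if (any(weights < 0)) stop("weights must be nonnegative")
  structure(list(centers = centers, exponents = exponents, weights = weights),
            class = "xcw_toygauss")
}

#' @rdname toy_gaussian_model
#' @param model an `xcw_toygauss`.
#' @param q reciprocal vector(s) in 1/bohr (length 3, or n x 3 matrix).
#' @return Complex structure factor(s).
#' @export
toy_gaussian_structure_factor <- function(model, q) {
  q <- matrix(q, ncol = 3)
  out <- complex(nrow(q))
  for (j in seq_along(model$weights)) {
    ph <- 2 * pi * as.vector(q %*% model$centers[j, ])
    q2 <- rowSums(q^2)
    out <- out + model$weights[j] * exp(1i * ph) *
      exp(-pi^2 * q2 / model$exponents[j])
  }
  out
}

#' Reference amplitude sets
#'
#' Fills the `F_obs` column of a reflection set with the amplitudes of a
#' method-labelled density: the "observed data" of a subsequent constrained
#' fit.  All sigmas are 1 (theoretical constraints, no error model).
#'
#' @param density an `xcw_density` (e.g. the correlated benchmark).
#' @param refs an `xcw_reflections`.
#' @param blocks optional precomputed [ft_ao_pair_integrals()] for the same
#'   basis/reflection pair (computed if missing).
#' @return The reflection set with `F_obs` filled and `sigma = 1`.
#' @export
make_reference_amplitudes <- function(density, refs, blocks = NULL) {
  if (is.null(blocks)) blocks <- ft_ao_pair_integrals(density$basis, refs)
  if (!identical(dim(blocks$M)[2], nrow(refs$hkl)) ||
      !isTRUE(all.equal(blocks$refs$hkl[, 1:3], refs$hkl[, 1:3]))) {
    stop("FT blocks were computed for a different reflection set")
  }
  F <- structure_factors_from_density(density, blocks)
  refs$hkl$F_obs <- Mod(F)
  refs$hkl$sigma <- 1
  refs$method <- density$method
  refs
}
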