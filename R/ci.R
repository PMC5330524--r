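# Correlated one-particle densities from determinant CI, plus the RHF
# density in the same container, as method-labelled results.

# four-index AO->MO transform of the chemist-notation ERI tensor
mo_transform <- function(ints, C) {
  n <- ints$nbf
  rot1 <- function(x) {
    y <- crossprod(C, matrix(x, n, n^3))
    aperm(array(y, c(n, n, n, n)), c(2, 3, 4, 1))
  }
  t4 <- rot1(array(ints$eri, c(n, n, n, n)))
  t4 <- rot1(t4); t4 <- rot1(t4); t4 <- rot1(t4)
  list(h = t(C) %*% ints$h %*% C, eri = t4)
}

new_density <- function(method, P, energy, ints, relaxed = NA, details = list()) {
  structure(list(method = method, P = P, energy = energy,
                 basis = ints$basis, molecule = ints$molecule, ints = ints,
                 relaxed = relaxed, details = details),
            class = "xcw_density")
}

#' @export
print.xcw_density <- function(x, ...) {
  cat(sprintf("<%s density: E = %.8f hartree, basis %s, %d AOs>\n",
              x$method, x$energy, x$basis$name, x$basis$nbf))
  invisible(x)
}

check_density_invariants <- function(d, tol = 1e-8) {
  S <- d$ints$S
  tr <- sum(d$P * S)
  if (abs(tr - d$molecule$nelec) > tol * max(1, d$molecule$nelec)) {
    stop("density trace ", format(tr), " does not match electron count ",
         d$molecule$nelec)
  }
  # natural occupations must lie in [0, 2]
  X12 <- chol(S)
  occ <- eigen(X12 %*% d$P %*% t(X12), symmetric = TRUE, only.values = TRUE)$values
  if (min(occ) < -1e-6 || max(occ) > 2 + 1e-6) {
    stop("natural occupations outside [0, 2]: range ",
         format(min(occ)), " .. ", format(max(occ)))
  }
  invisible(TRUE)
}

#' Restricted Hartree-Fock one-particle density
#'
#' @param mol an [molecule()].
#' @param basis basis-set name or `xcw_basis`.
#' @param ints optional precomputed integral context.
#' @return An `xcw_density` with `method = "RHF"`; the density matrix `P` is
#'   the total (spin-summed) AO density, idempotent in the P S P = 2 P sense.
#' @export
rhf_density <- function(mol, basis = "sto-3g", ints = NULL) {
  r <- rhf(mol, basis, ints = ints)
  if (!r$converged) stop("RHF did not converge")
  d <- new_density("RHF", r$P, r$energy, r$ints, relaxed = NA,
                   details = list(scf = r))
  check_density_invariants(d)
  d
}

#' Correlated one-particle density (determinant CI)
#'
#' Runs RHF, transforms the integrals to the MO basis and solves the
#' configuration-interaction problem in the determinant basis: CISD keeps
#' all single and double substitutions out of the closed-shell reference;
#' FCI enumerates the complete determinant space and is admitted only for
#' systems with at most 4 electrons.  The returned one-particle density is
#' the expectation value of the converged CI state (a variational,
#' unrelaxed-by-construction density; for variational CI no orbital-response
#' correction is involved).  For 2-electron systems CISD and FCI coincide.
#'
#' @param mol an [molecule()].
#' @param basis basis-set name or `xcw_basis`.
#' @param method `"CISD"` or `"FCI"`.
#' @param ints optional precomputed integral context.
#' @return An `xcw_density` with the AO-basis spin-summed density matrix,
#'   total energy, and CI details (`n_det`, reference weight `c0`).
#' @export
correlated_density <- function(mol, basis = "sto-3g",
                               method = c("CISD", "FCI"), ints = NULL) {
  method <- match.arg(method)
  r <- rhf(mol, basis, ints = ints)
  if (!r$converged) stop("reference RHF did not converge")
  nelec <- r$ints$molecule$nelec
  if (method == "FCI" && nelec > 4) {
    stop("FCI is reserved for systems with at most 4 electrons (got ",
         nelec, "); use CISD")
  }
  mo <- mo_transform(r$ints, r$C)
  res <- cpp_ci_solve(mo$h, as.numeric(mo$eri), r$ints$nbf, r$nocc,
                      tolower(method), 1e-10)
  Pmo <- res$rdm1
  P <- r$C %*% Pmo %*% t(r$C)
  d <- new_density(method, P, res$energy + r$ints$enuc, r$ints,
                   relaxed = FALSE,
                   details = list(n_det = res$n_det, c0 = res$c0,
                                  e_corr = res$energy + r$ints$enuc - r$energy,
                                  scf = r))
  check_density_invariants(d)
  d
}

#' Kohn-Sham DFT densities (optional stage, not provided)
#'
#' The package's built-in electronic-structure backend implements
#' Hartree-Fock and determinant CI only; no exchange-correlation functionals
#' are available.  This stub preserves the pipeline surface and raises an
#' explicit capability error.
#'
#' @param mol,basis,functional as in [rhf_density()].
#' @export
dft_density <- function(mol, basis = "sto-3g",
                        functional = c("BLYP", "B3LYP", "VSXC", "B1B95")) {
  functional <- match.arg(functional)
  stop("DFT functional ", functional,
       " is not available: the built-in backend implements RHF, CISD and FCI only")
}
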