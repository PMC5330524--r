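# X-ray constrained restricted Hartree-Fock: the chi^2 agreement statistic,
# the penalised energy functional J = E0 + lambda*(chi^2 - Delta), its exact
# density-matrix gradient (the constrained Fock operator), the
# self-consistent solver and warm-started lambda scans.

#' Constraint configuration
#'
#' Settings of the constrained fit.  For theoretical constraints the scale
#' factor `eta` and all standard uncertainties are 1; the number of
#' adjustable parameters `Np` is 1 (the external multiplier itself); `delta`
#' is the target agreement and shifts the functional by a constant without
#' ever moving its minimizer.
#'
#' @param lambda constraint weight (dimensionless, >= 0).
#' @param delta target chi^2 (constant offset in the functional).
#' @param eta amplitude scale factor (> 0, never refined here).
#' @param Np number of adjustable parameters (must stay below N_r).
#' @param phase_tol amplitudes below this have no defined phase; their
#'   constraint contribution is dropped for the iteration.
#' @return A list of class `xcw_config`.
#' @export
constraint_config <- function(lambda = 0, delta = 1, eta = 1, Np = 1L,
                              phase_tol = 1e-10) {
  if (lambda < 0) stop("lambda must be nonnegative")
  if (eta <= 0) stop("eta must be positive")
  structure(list(lambda = lambda, delta = delta, eta = eta, Np = as.integer(Np),
                 phase_tol = phase_tol),
            class = "xcw_config")
}

#' Chi-squared agreement statistic
#'
#' \deqn{\chi^2 = \frac{1}{N_r - N_p} \sum_h
#'       \frac{(\eta|F_h^{calc}| - |F_h^{obs}|)^2}{\sigma_h^2}}
#'
#' @param calc,obs amplitude vectors (same length N_r).
#' @param sigma standard uncertainties (recycled).
#' @param eta scale factor.
#' @param Np number of adjustable parameters; requires N_r > Np.
#' @return The dimensionless statistic (0 iff eta*calc == obs everywhere).
#' @export
chi_squared <- function(calc, obs, sigma = 1, eta = 1, Np = 1L) {
  Nr <- length(calc)
  if (length(obs) != Nr) stop("calc and obs must have the same length")
  if (Nr <= Np) stop("need more reflections than adjustable parameters (N_r > N_p)")
  sum(((eta * calc - obs) / sigma)^2) / (Nr - Np)
}

#' The penalised wavefunction-fitting functional
#'
#' J = E0 + lambda * (chi^2 - delta).  At lambda = 0 this is the plain
#' Hartree-Fock energy; delta only shifts J by a constant.
#'
#' @param E0 determinant energy, hartree.
#' @param chi2 agreement statistic.
#' @param cfg a [constraint_config()].
#' @return J (hartree-equivalent).
#' @export
jayatilaka_functional <- function(E0, chi2, cfg) {
  E0 + cfg$lambda * (chi2 - cfg$delta)
}

#' Constraint coefficients K_h
#'
#' The amplitude-residual weights entering the constrained Fock operator:
#' \deqn{K_h = \frac{2\eta}{N_r - N_p}\,
#'       \frac{\eta|F_h^{calc}| - |F_h^{obs}|}{\sigma_h^2}.}
#' Together with the calculated phase u_h = F_h/|F_h| they make the exact
#' derivative of chi^2 with respect to the density matrix:
#' d(chi^2)/dP = sum_h K_h Re(conj(u_h) I_h).  Reflections whose calculated
#' amplitude is below `phase_tol` have no defined phase and get K_h = 0.
#'
#' @param F_calc complex calculated structure factors.
#' @param obs observed amplitudes.
#' @param sigma standard uncertainties (recycled).
#' @param cfg a [constraint_config()].
#' @return List with `K` (numeric), `u` (complex unit phases, 0 where
#'   undefined) and `n_phaseless` (count of dropped reflections).
#' @export
constraint_coefficients <- function(F_calc, obs, sigma = 1, cfg = constraint_config()) {
  Nr <- length(F_calc)
  if (Nr <= cfg$Np) stop("need N_r > N_p")
  A <- Mod(F_calc)
  sig2 <- rep_len(sigma, Nr)^2
  K <- 2 * cfg$eta * (cfg$eta * A - obs) / (sig2 * (Nr - cfg$Np))
  ok <- A > cfg$phase_tol
  u <- rep(0 + 0i, Nr)
  u[ok] <- F_calc[ok] / A[ok]
  K[!ok] <- 0
  list(K = K, u = u, n_phaseless = sum(!ok))
}

#' Assemble the constrained Fock matrix
#'
#' F_eff = F_fock + lambda * sum_h K_h Re(conj(u_h) I_h); the constraint
#' term is the phase-resolved combination of the hermitian real and
#' imaginary parts of the structure-factor operator and is exactly symmetric
#' for real AO products.
#'
#' @param F_fock unconstrained Fock matrix (real symmetric).
#' @param blocks an [ft_ao_pair_integrals()] result.
#' @param K,u outputs of [constraint_coefficients()].
#' @param lambda constraint weight.
#' @return Real symmetric matrix of the same dimension.
#' @export
build_constrained_fock <- function(F_fock, blocks, K, u, lambda) {
  n <- blocks$nbf
  if (nrow(F_fock) != n) stop("Fock matrix dimension does not match FT blocks")
  F_fock + lambda * constraint_matrix(blocks, K, u)
}

# sum_h K_h Re(conj(u_h) I_h), unpacked from the stored lower triangles into
# a full symmetric matrix
constraint_matrix <- function(blocks, K, u) {
  n <- blocks$nbf
  v <- Re(blocks$M %*% (K * Conj(u)))
  cmat <- matrix(0, n, n)
  cmat[blocks$lowidx] <- v
  cmat <- cmat + t(cmat)
  diag(cmat) <- diag(cmat) / 2
  cmat
}

# constraint closure used inside the SCF kernel
make_constraint <- function(blocks, obs, sigma, cfg) {
  n <- blocks$nbf
  force(obs); force(sigma)
  function(P) {
    Fc <- as.vector(crossprod(blocks$M, P[blocks$lowidx] * blocks$wpack))
    A <- Mod(Fc)
    chi2 <- chi_squared(A, obs, sigma, cfg$eta, cfg$Np)
    cc <- constraint_coefficients(Fc, obs, sigma, cfg)
    cmat <- constraint_matrix(blocks, cc$K, cc$u)
    list(mat = cfg$lambda * cmat,
         penalty = cfg$lambda * (chi2 - cfg$delta),
         chi2 = chi2, n_phaseless = cc$n_phaseless)
  }
}

#' Solve the X-ray constrained SCF problem
#'
#' Minimizes J = E0 + lambda*(chi^2 - delta) over closed-shell Slater
#' determinants by self-consistent iteration of the constrained Fock
#' operator, with DIIS acceleration and density damping in the early
#' cycles.  At lambda = 0 the solution is the unconstrained RHF state.
#'
#' @param mol an [molecule()] (ignored if `ints` given).
#' @param basis basis-set name or `xcw_basis`.
#' @param refs an `xcw_reflections` with `F_obs` filled (the constraints).
#' @param cfg a [constraint_config()].
#' @param blocks optional precomputed FT blocks for (basis, refs).
#' @param ints optional precomputed integral context.
#' @param P0 optional starting density (warm start).
#' @param max_iter,tol_de,tol_err convergence controls: DIIS commutator norm
#'   below `tol_err` and functional change below `tol_de`.
#' @return Object of class `xcw_xcwf`: MO coefficients, total density `P`,
#'   energy `E0` (hartree, nuclear repulsion included), `chi2`, `J`,
#'   `lambda`, `s_max`, iteration count and convergence flag, plus a
#'   method-labelled `xcw_density` in `$density`.
#' @export
xc_scf_solve <- function(mol, basis, refs, cfg = constraint_config(),
                         blocks = NULL, ints = NULL, P0 = NULL,
                         max_iter = 300L, tol_de = 1e-8, tol_err = 1e-7) {
  if (is.null(ints)) ints <- compute_integrals(mol, basis)
  nocc <- ints$molecule$nelec %/% 2L
  if (nrow(refs$hkl) < 2) stop("need at least two reflections (N_r > N_p)")
  if (anyNA(refs$hkl$F_obs)) stop("reflection set has no observed amplitudes")
  if (is.null(blocks)) blocks <- ft_ao_pair_integrals(ints$basis, refs)
  constraint <- if (cfg$lambda > 0) {
    make_constraint(blocks, refs$hkl$F_obs, refs$hkl$sigma, cfg)
  } else NULL
  res <- scf_kernel(ints, nocc, constraint = constraint, P0 = P0,
                    max_iter = max_iter, tol_de = tol_de, tol_err = tol_err)
  if (is.na(res$chi2)) {
    # lambda = 0: report the diagnostic chi2 of the unconstrained solution
    Fc <- structure_factors_from_density(res$P, blocks)
    res$chi2 <- chi_squared(Mod(Fc), refs$hkl$F_obs, refs$hkl$sigma,
                            cfg$eta, cfg$Np)
    res$J <- res$E0 + cfg$lambda * (res$chi2 - cfg$delta)
  }
  if (!res$converged) {
    warning(sprintf("constrained SCF (lambda = %g) not converged after %d iterations (err %.2e)",
                    cfg$lambda, res$n_iter, res$grad_err))
  }
  dens <- new_density(sprintf("XC-RHF(lambda=%g)", cfg$lambda), res$P, res$E0,
                      ints, relaxed = NA,
                      details = list(lambda = cfg$lambda, chi2 = res$chi2))
  structure(list(C = res$C, mo_coefficients = res$C[, seq_len(nocc), drop = FALSE],
                 P = res$P, E0 = res$E0, chi2 = res$chi2, J = res$J,
                 lambda = cfg$lambda, s_max = refs$s_max, nocc = nocc,
                 n_iterations = res$n_iter, converged = res$converged,
                 grad_err = res$grad_err, density = dens, cfg = cfg),
            class = "xcw_xcwf")
}

#' @export
print.xcw_xcwf <- function(x, ...) {
  cat(sprintf("<XC-RHF: lambda = %g, s_max = %.2f 1/A, E0 = %.8f, chi2 = %.6g, %s>\n",
              x$lambda, x$s_max, x$E0, x$chi2,
              if (x$converged) "converged" else "NOT CONVERGED"))
  invisible(x)
}

#' Warm-started scan over the constraint weight
#'
#' Solves the constrained SCF problem along an ascending lambda grid,
#' starting each point from the previous point's density (the robust path
#' to large weights; convergence from scratch becomes difficult as lambda
#' grows).  chi^2 is expected to be non-increasing along the scan;
#' violations are flagged as convergence failures in the result.
#'
#' @param mol,basis,refs,cfg,blocks,ints as in [xc_scf_solve()].
#' @param lambdas ascending grid of weights, typically `seq(0, 10, 0.5)`.
#' @param ... further arguments to [xc_scf_solve()].
#' @return List of class `xcw_scan`: one `xcw_xcwf` per grid point.
#' @export
lambda_scan <- function(mol, basis, refs, lambdas = seq(0, 10, by = 0.5),
                        cfg = constraint_config(), blocks = NULL, ints = NULL,
                        ...) {
  if (is.unsorted(lambdas)) stop("lambda grid must be ascending")
  if (is.null(ints)) ints <- compute_integrals(mol, basis)
  if (is.null(blocks)) blocks <- ft_ao_pair_integrals(ints$basis, refs)
  out <- vector("list", length(lambdas))
  P0 <- NULL
  chi_prev <- Inf
  for (i in seq_along(lambdas)) {
    cfg_i <- cfg
    cfg_i$lambda <- lambdas[i]
    res <- xc_scf_solve(mol, basis, refs, cfg_i, blocks = blocks, ints = ints,
                        P0 = P0, ...)
    if (res$converged && res$chi2 > chi_prev + 1e-8) {
      warning(sprintf("chi^2 increased along the scan at lambda = %g", lambdas[i]))
      res$converged <- FALSE
    }
    if (res$converged) chi_prev <- res$chi2
    out[[i]] <- res
    P0 <- res$P
  }
  structure(out, class = "xcw_scan",
            lambdas = lambdas, s_max = refs$s_max)
}

#' @export
print.xcw_scan <- function(x, ...) {
  cat(sprintf("<lambda scan: %d points, s_max = %.2f 1/A>\n",
              length(x), attr(x, "s_max")))
  df <- data.frame(lambda = vapply(x, `[[`, 0, "lambda"),
                   E0 = vapply(x, `[[`, 0, "E0"),
                   chi2 = vapply(x, `[[`, 0, "chi2"),
                   converged = vapply(x, `[[`, TRUE, "converged"))
  print(df, row.names = FALSE)
  invisible(x)
}
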