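# Restricted Hartree-Fock engine with DIIS acceleration.  The same kernel
# drives unconstrained RHF and the X-ray constrained SCF: the constraint term
# enters as an additive, density-dependent symmetric matrix in the effective
# Fock operator.

fock_matrices <- function(ints) {
  n <- ints$nbf
  if (is.null(ints$.Jmat)) {
    ints$.Jmat <- matrix(ints$eri, n * n, n * n)
    ints$.Kmat <- matrix(aperm(array(ints$eri, c(n, n, n, n)), c(1, 3, 2, 4)),
                         n * n, n * n)
  }
  ints
}

# two-electron part of the Fock matrix for total density P (closed shell):
# G(P) = J(P) - K(P)/2
g_matrix <- function(ints, P) {
  n <- ints$nbf
  vp <- as.numeric(P)
  matrix(ints$.Jmat %*% vp - 0.5 * ints$.Kmat %*% vp, n, n)
}

# diagonalize a symmetric operator in the orthonormalized AO basis and return
# MO coefficients ordered by ascending orbital energy (R's eigen() sorts the
# other way around)
solve_fock <- function(Feff, X) {
  es <- eigen(t(X) %*% Feff %*% X, symmetric = TRUE)
  ord <- order(es$values)
  list(C = (X %*% es$vectors)[, ord, drop = FALSE], eps = es$values[ord])
}

core_guess <- function(ints, nocc) {
  mo <- solve_fock(ints$h, ints$X)
  2 * tcrossprod(mo$C[, seq_len(nocc), drop = FALSE])
}

# Generic closed-shell SCF loop.  `constraint` is NULL for plain RHF or a
# function(P) returning list(mat = symmetric AO matrix to add to the Fock
# operator, penalty = lambda * (chi2 - delta), chi2 = chi2) for the
# constrained problem.
scf_kernel <- function(ints, nocc, constraint = NULL, P0 = NULL,
                       max_iter = 300L, tol_de = 1e-8, tol_err = 1e-7,
                       diis_space = 8L) {
  ints <- fock_matrices(ints)
  n <- ints$nbf
  S <- ints$S; X <- ints$X; h <- ints$h
  P <- if (is.null(P0)) core_guess(ints, nocc) else P0
  diis_F <- list(); diis_e <- list()
  J_old <- Inf
  converged <- FALSE
  err_norm <- NA_real_
  chi2 <- NA_real_
  E0 <- NA_real_
  C <- NULL; eps <- NULL

  for (iter in seq_len(max_iter)) {
    F0 <- h + g_matrix(ints, P)
    E0 <- 0.5 * sum(P * (h + F0)) + ints$enuc
    Feff <- F0
    penalty <- 0
    if (!is.null(constraint)) {
      cst <- constraint(P)
      Feff <- Feff + cst$mat
      penalty <- cst$penalty
      chi2 <- cst$chi2
    }
    Jfun <- E0 + penalty

    err <- Feff %*% P %*% S - S %*% P %*% Feff
    err <- t(X) %*% err %*% X
    err_norm <- max(abs(err))

    if (abs(Jfun - J_old) < tol_de && err_norm < tol_err) {
      converged <- TRUE
    }

    # DIIS extrapolation of the effective Fock operator
    diis_F[[length(diis_F) + 1]] <- Feff
    diis_e[[length(diis_e) + 1]] <- err
    if (length(diis_F) > diis_space) {
      diis_F <- diis_F[-1]; diis_e <- diis_e[-1]
    }
    m <- length(diis_F)
    if (m > 1) {
      B <- matrix(0, m + 1, m + 1)
      for (i in seq_len(m)) for (j in seq_len(m)) {
        B[i, j] <- sum(diis_e[[i]] * diis_e[[j]])
      }
      B[m + 1, seq_len(m)] <- B[seq_len(m), m + 1] <- -1
      rhs <- c(rep(0, m), -1)
      w <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
      if (!is.null(w) && all(is.finite(w))) {
        Feff <- Reduce(`+`, Map(`*`, diis_F, w))
      } else {
        diis_F <- diis_F[m]; diis_e <- diis_e[m]
      }
    }

    mo <- solve_fock(Feff, X)
    C <- mo$C
    eps <- mo$eps
    Pnew <- 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
    if (converged) { P <- Pnew; break }
    # light density damping in the first cycles stabilises large penalties
    P <- if (iter <= 3 && m <= 1) 0.7 * Pnew + 0.3 * P else Pnew
    J_old <- Jfun
  }

  list(C = C, eps = eps, P = P, E0 = E0, chi2 = chi2, J = E0 + penalty,
       n_iter = iter, converged = converged, grad_err = err_norm)
}

#' Restricted Hartree-Fock single point
#'
#' Closed-shell RHF with DIIS convergence acceleration (commutator norm
#' below `tol_err`, energy change below `tol_de`).
#'
#' @param mol an [molecule()] (even electron count).
#' @param basis basis-set name or `xcw_basis`.
#' @param ints optionally a precomputed [compute_integrals()] context.
#' @param P0 optional starting total density matrix.
#' @param max_iter,tol_de,tol_err convergence controls.
#' @return Object of class `xcw_scf`: MO coefficients `C`, orbital energies
#'   `eps`, total density `P` (so that tr(P S) equals the electron count),
#'   total energy `energy` (hartree, nuclear repulsion included),
#'   `converged` flag and the integral context `ints`.
#' @export
rhf <- function(mol, basis = "sto-3g", ints = NULL, P0 = NULL,
                max_iter = 300L, tol_de = 1e-10, tol_err = 1e-8) {
  if (is.null(ints)) ints <- compute_integrals(mol, basis)
  nocc <- ints$molecule$nelec %/% 2L
  res <- scf_kernel(ints, nocc, P0 = P0, max_iter = max_iter,
                    tol_de = tol_de, tol_err = tol_err)
  if (!res$converged) warning("RHF did not converge in ", max_iter, " iterations")
  structure(list(C = res$C, eps = res$eps, P = res$P, energy = res$E0,
                 nocc = nocc, converged = res$converged,
                 n_iter = res$n_iter, ints = ints),
            class = "xcw_scf")
}

#' @export
print.xcw_scf <- function(x, ...) {
  cat(sprintf("<RHF: E = %.8f hartree, %d AOs, %s in %d iterations>\n",
              x$energy, x$ints$nbf,
              if (x$converged) "converged" else "NOT CONVERGED", x$n_iter))
  invisible(x)
}
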