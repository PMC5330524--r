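# Geometry optimization on the package's own energy surfaces.  Diatomics
# reduce to a one-dimensional bond-length search; polyatomics are relaxed
# in Cartesian coordinates with a quasi-Newton optimizer over central-
# difference gradients (adequate for the few-atom fixtures this package
# studies).

energy_at <- function(mol, basis, method) {
  switch(method,
         RHF = rhf(mol, basis)$energy,
         CISD = correlated_density(mol, basis, "CISD")$energy,
         FCI = correlated_density(mol, basis, "FCI")$energy,
         stop("unknown method: ", method))
}

#' Optimize a molecular geometry
#'
#' Minimizes the total energy at the requested level.  Diatomics use a 1-D
#' line search on the bond length; polyatomics a BFGS search over all
#' Cartesian coordinates with central-difference gradients.  The
#' postcondition (maximum nuclear gradient below `grad_tol`
#' hartree/bohr) is verified by central differences and reported.
#'
#' @param mol starting [molecule()].
#' @param basis basis-set name.
#' @param method `"RHF"`, `"CISD"` or `"FCI"`.
#' @param grad_tol convergence threshold on the max Cartesian gradient.
#' @param fd_step finite-difference step, bohr.
#' @param maxit optimizer iteration cap.
#' @return The optimized `xcw_molecule`, with attributes `energy`,
#'   `max_grad` and `converged`.
#' @export
optimize_geometry <- function(mol, basis, method = c("RHF", "CISD", "FCI"),
                              grad_tol = 1e-5, fd_step = 2e-3, maxit = 200L) {
  method <- match.arg(method)
  n <- length(mol$Z)
  if (n == 2) {
    dir <- mol$xyz[2, ] - mol$xyz[1, ]
    r0 <- sqrt(sum(dir^2))
    dir <- dir / r0
    cen <- (mol$xyz[1, ] + mol$xyz[2, ]) / 2
    efun <- function(r) {
      m <- molecule(mol$Z, rbind(cen - dir * r / 2, cen + dir * r / 2),
                    charge = mol$charge, comment = mol$comment)
      energy_at(m, basis, method)
    }
    opt <- stats::optimize(efun, interval = c(max(0.4, 0.5 * r0), 2.5 * r0),
                           tol = 1e-7)
    r <- opt$minimum
    out <- molecule(mol$Z, rbind(cen - dir * r / 2, cen + dir * r / 2),
                    charge = mol$charge,
                    comment = sprintf("optimized %s/%s, r = %.6f bohr", method, basis, r))
    e <- opt$objective
    # quadratic-fit gradient check along the bond
    g <- (efun(r + fd_step) - efun(r - fd_step)) / (2 * fd_step)
    attr(out, "energy") <- e
    attr(out, "max_grad") <- abs(g)
    attr(out, "converged") <- abs(g) < grad_tol
    return(out)
  }
  x0 <- as.numeric(mol$xyz)
  efun <- function(x) {
    energy_at(molecule(mol$Z, matrix(x, n, 3), charge = mol$charge), basis, method)
  }
  gfun <- function(x) {
    g <- numeric(length(x))
    for (i in seq_along(x)) {
      xp <- x; xp[i] <- x[i] + fd_step
      xm <- x; xm[i] <- x[i] - fd_step
      g[i] <- (efun(xp) - efun(xm)) / (2 * fd_step)
    }
    g
  }
  opt <- stats::optim(x0, efun, gfun, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  g <- gfun(opt$par)
  out <- molecule(mol$Z, matrix(opt$par, n, 3), charge = mol$charge,
                  comment = sprintf("optimized %s/%s", method, basis))
  attr(out, "energy") <- opt$value
  attr(out, "max_grad") <- max(abs(g))
  attr(out, "converged") <- max(abs(g)) < grad_tol
  if (!attr(out, "converged")) {
    warning(sprintf("geometry optimization left a residual gradient of %.2e hartree/bohr",
                    max(abs(g))))
  }
  out
}
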