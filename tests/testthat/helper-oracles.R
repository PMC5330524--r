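# Independent oracles used across the test suite.  These deliberately avoid
# the package's Hermite-expansion code paths: closed-form s-type integrals,
# quadrature, and explicitly constructed CI matrices.

# --- closed-form s-type Gaussian integrals (textbook formulas) -----------

s_overlap_prim <- function(a, b, RA, RB) {
  p <- a + b
  r2 <- sum((RA - RB)^2)
  (pi / p)^1.5 * exp(-a * b / p * r2)
}

s_kinetic_prim <- function(a, b, RA, RB) {
  p <- a + b
  r2 <- sum((RA - RB)^2)
  a * b / p * (3 - 2 * a * b / p * r2) * (pi / p)^1.5 * exp(-a * b / p * r2)
}

boys0 <- function(x) ifelse(x < 1e-12, 1, 0.5 * sqrt(pi / x) * erf_sqrt(x))
erf_sqrt <- function(x) 2 * pnorm(sqrt(2 * x)) - 1  # erf(sqrt(x))

s_nuclear_prim <- function(a, b, RA, RB, RC, Z) {
  p <- a + b
  r2 <- sum((RA - RB)^2)
  P <- (a * RA + b * RB) / p
  -Z * 2 * pi / p * exp(-a * b / p * r2) * boys0(p * sum((P - RC)^2))
}

s_eri_prim <- function(a, b, c, d, RA, RB, RC, RD) {
  p <- a + b; q <- c + d
  P <- (a * RA + b * RB) / p
  Q <- (c * RC + d * RD) / q
  2 * pi^2.5 / (p * q * sqrt(p + q)) *
    exp(-a * b / p * sum((RA - RB)^2)) *
    exp(-c * d / q * sum((RC - RD)^2)) *
    boys0(p * q / (p + q) * sum((P - Q)^2))
}

# contracted s-only integrals for a list of shells (exps, coefs, center),
# coefficients already normalized as in the package
oracle_s_matrices <- function(shells, Zs, pos) {
  n <- length(shells)
  S <- T <- V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    si <- shells[[i]]; sj <- shells[[j]]
    for (pa in seq_along(si$exps)) for (pb in seq_along(sj$exps)) {
      cc <- si$coefs[pa] * sj$coefs[pb]
      S[i, j] <- S[i, j] + cc * s_overlap_prim(si$exps[pa], sj$exps[pb], si$center, sj$center)
      T[i, j] <- T[i, j] + cc * s_kinetic_prim(si$exps[pa], sj$exps[pb], si$center, sj$center)
      for (nu in seq_along(Zs)) {
        V[i, j] <- V[i, j] + cc * s_nuclear_prim(si$exps[pa], sj$exps[pb],
                                                 si$center, sj$center, pos[nu, ], Zs[nu])
      }
    }
  }
  list(S = S, T = T, V = V)
}

oracle_s_eri <- function(sh, i, j, k, l) {
  out <- 0
  si <- sh[[i]]; sj <- sh[[j]]; sk <- sh[[k]]; sl <- sh[[l]]
  for (pa in seq_along(si$exps)) for (pb in seq_along(sj$exps))
    for (pc in seq_along(sk$exps)) for (pd in seq_along(sl$exps)) {
      out <- out + si$coefs[pa] * sj$coefs[pb] * sk$coefs[pc] * sl$coefs[pd] *
        s_eri_prim(si$exps[pa], sj$exps[pb], sk$exps[pc], sl$exps[pd],
                   si$center, sj$center, sk$center, sl$center)
    }
  out
}

# --- Gauss-Legendre nodes/weights (Golub-Welsch) -------------------------

gauss_legendre <- function(n, a = -1, b = 1) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  es <- eigen(J, symmetric = TRUE)
  x <- es$values
  w <- 2 * es$vectors[1, ]^2
  list(x = (b - a) / 2 * x + (a + b) / 2, w = (b - a) / 2 * w)
}

# --- independent AO evaluator (s and p shells only) ----------------------

oracle_ao_values <- function(shells, pts) {
  vals <- NULL
  for (sh in shells) {
    d <- sweep(pts, 2, sh$center)
    r2 <- rowSums(d^2)
    rad <- rowSums(sapply(seq_along(sh$exps),
                          function(p) sh$coefs[p] * exp(-sh$exps[p] * r2)))
    if (sh$l == 0) {
      vals <- cbind(vals, rad)
    } else if (sh$l == 1) {
      vals <- cbind(vals, d[, 1] * rad, d[, 2] * rad, d[, 3] * rad)
    } else stop("oracle handles s and p shells only")
  }
  vals
}

# --- shared fixtures ------------------------------------------------------

h2_fixture <- function() fixture_geometry("H2_test")
cell10 <- function() unit_cell(10)

# memoised heavyweight pipeline pieces, shared across test files
.prod_cache <- new.env(parent = emptyenv())

prod_get <- function(key, compute) {
  if (!exists(key, envir = .prod_cache)) assign(key, compute(), envir = .prod_cache)
  get(key, envir = .prod_cache)
}

PROD_BASIS <- "6-31gdp"

prod_system <- function(name) {
  prod_get(paste0("sys_", name), function() {
    mol <- fixture_geometry(name)
    ints <- compute_integrals(mol, PROD_BASIS)
    list(mol = mol,
         ints = ints,
         rhf = rhf_density(mol, PROD_BASIS, ints = ints),
         corr = correlated_density(mol, PROD_BASIS, "CISD", ints = ints))
  })
}

# warm-started scan for one production system at one resolution, with the
# TI evaluated at each lambda point; cached across test files
prod_scan <- function(name, s_max, lambdas = seq(0, 10, by = 0.5)) {
  key <- sprintf("scan_%s_%.2f_%d", name, s_max, length(lambdas))
  prod_get(key, function() {
    sys <- prod_system(name)
    bond <- fixture_bonds(name)[[1]]
    refs <- generate_reflection_set(cell10(), s_max)
    blocks <- ft_ao_pair_integrals(sys$ints$basis, refs)
    refs <- make_reference_amplitudes(sys$corr, refs, blocks)
    scan <- lambda_scan(sys$mol, PROD_BASIS, refs, lambdas,
                        blocks = blocks, ints = sys$ints)
    rho_h <- find_bcp(sys$rhf, bond[1], bond[2])$rho
    rho_c <- find_bcp(sys$corr, bond[1], bond[2])$rho
    ti <- vapply(scan, function(r) {
      topological_index(find_bcp(r$density, bond[1], bond[2])$rho, rho_h, rho_c)
    }, 0)
    list(scan = scan, ti = ti, lambdas = lambdas,
         converged = vapply(scan, `[[`, TRUE, "converged"))
  })
}
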