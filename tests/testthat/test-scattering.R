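# Analytic Fourier transforms of AO pair densities and structure factors.

test_that("zero-frequency FT block equals the AO overlap matrix", {
  bs <- build_basis(fixture_geometry("H2_test"), "6-31g")
  ints <- compute_integrals(bs$molecule, bs)
  M0 <- xcwfit:::cpp_ft_blocks(bs$shells, matrix(0, 1, 3))
  n <- bs$nbf
  packedS <- ints$S[lower.tri(ints$S, diag = TRUE)]
  expect_equal(Re(M0[, 1]), packedS, tolerance = 1e-12)
  expect_equal(max(abs(Im(M0[, 1]))), 0)
})

test_that("I(-h) is the complex conjugate of I(h) on a full sphere", {
  bs <- build_basis(fixture_geometry("water"), "sto-3g")
  refs <- generate_reflection_set(unit_cell(10), 0.15, friedel = "full-sphere")
  blocks <- ft_ao_pair_integrals(bs, refs)
  H <- as.matrix(refs$hkl[, 1:3])
  key <- apply(H, 1, paste, collapse = ",")
  anti <- match(apply(-H, 1, paste, collapse = ","), key)
  expect_false(anyNA(anti))
  expect_equal(blocks$M[, anti], Conj(blocks$M), tolerance = 1e-12)
})

test_that("single-Gaussian FT diagonal matches adaptive quadrature", {
  # one normalized 1s Gaussian, diagonal entry at q: the product is a
  # Gaussian of exponent 2*alpha; integrate each axis with stats::integrate
  alpha <- 0.8
  sh <- list(list(l = 0L, center = c(0.3, -0.2, 0.5),
                  exps = alpha, coefs = xcwfit:::cpp_prim_norm(alpha, 0L, 0L, 0L)))
  q <- c(0.21, -0.13, 0.34)
  M <- xcwfit:::cpp_ft_blocks(sh, matrix(q, 1, 3))
  a2 <- 2 * alpha
  f1d <- function(qx, cx) {
    re <- integrate(function(x) exp(-a2 * (x - cx)^2) * cos(2 * pi * qx * x),
                    -Inf, Inf, rel.tol = 1e-12)$value
    im <- integrate(function(x) exp(-a2 * (x - cx)^2) * sin(2 * pi * qx * x),
                    -Inf, Inf, rel.tol = 1e-12)$value
    complex(real = re, imaginary = im)
  }
  nrm <- xcwfit:::cpp_prim_norm(alpha, 0L, 0L, 0L)^2
  want <- nrm * f1d(q[1], 0.3) * f1d(q[2], -0.2) * f1d(q[3], 0.5)
  expect_equal(M[1, 1], want, tolerance = 1e-8)
})

test_that("p-d cross FT block matches axis-separable quadrature", {
  # exercises the Hermite expansion at l > 0: one p shell and one d shell
  shp <- list(l = 1L, center = c(0, 0, 0), exps = 0.9,
              coefs = xcwfit:::cpp_prim_norm(0.9, 1L, 0L, 0L))
  shd <- list(l = 2L, center = c(0.4, 0.1, -0.3), exps = 1.1,
              coefs = xcwfit:::cpp_prim_norm(1.1, 2L, 0L, 0L))
  q <- c(0.17, 0.25, -0.08)
  M <- xcwfit:::cpp_ft_blocks(list(shp, shd), matrix(q, 1, 3))
  # entry (pz, dxz): row 3 (px,py,pz), col 3+3 = dxz is component 3 of d
  n <- 9
  full <- matrix(0 + 0i, n, n)
  full[lower.tri(full, diag = TRUE)] <- M[, 1]
  full <- full + t(full); diag(full) <- diag(full) / 2
  f1d <- function(qx, pow1, c1, a1, pow2, c2, a2) {
    g <- function(x) (x - c1)^pow1 * (x - c2)^pow2 * exp(-a1 * (x - c1)^2 - a2 * (x - c2)^2)
    re <- integrate(function(x) g(x) * cos(2 * pi * qx * x), -Inf, Inf, rel.tol = 1e-12)$value
    im <- integrate(function(x) g(x) * sin(2 * pi * qx * x), -Inf, Inf, rel.tol = 1e-12)$value
    complex(real = re, imaginary = im)
  }
  nrm <- xcwfit:::cpp_prim_norm(0.9, 1L, 0L, 0L) * xcwfit:::cpp_prim_norm(1.1, 2L, 0L, 0L)
  # pz at origin times dxz at center2: x-power (0,1), y (0,0), z (1,1)
  want <- nrm * f1d(q[1], 0, 0, 0.9, 1, 0.4, 1.1) *
    f1d(q[2], 0, 0, 0.9, 0, 0.1, 1.1) *
    f1d(q[3], 1, 0, 0.9, 1, -0.3, 1.1)
  expect_equal(full[3, 3 + 3], want, tolerance = 1e-8)
})

test_that("toy Gaussian model matches its closed form and quadrature", {
  m1 <- toy_gaussian_model(c(0, 0, 0), 1.3, 2)
  expect_equal(toy_gaussian_structure_factor(m1, c(0, 0, 0)), 2 + 0i)
  F <- toy_gaussian_structure_factor(m1, c(0.3, 0.1, -0.2))
  expect_equal(Im(F), 0)
  expect_gt(Re(F), 0)
  # two displaced Gaussians vs numerical quadrature (axis-separable)
  m2 <- toy_gaussian_model(rbind(c(0.5, 0, 0), c(-0.3, 0.2, 0.1)),
                           c(0.9, 1.4), c(1.5, 0.5))
  q <- c(0.12, -0.31, 0.22)
  f1d <- function(qx, cx, a) {
    nr <- sqrt(a / pi)
    re <- integrate(function(x) nr * exp(-a * (x - cx)^2) * cos(2 * pi * qx * x),
                    -Inf, Inf, rel.tol = 1e-13)$value
    im <- integrate(function(x) nr * exp(-a * (x - cx)^2) * sin(2 * pi * qx * x),
                    -Inf, Inf, rel.tol = 1e-13)$value
    complex(real = re, imaginary = im)
  }
  want <- 1.5 * f1d(q[1], 0.5, 0.9) * f1d(q[2], 0, 0.9) * f1d(q[3], 0, 0.9) +
    0.5 * f1d(q[1], -0.3, 1.4) * f1d(q[2], 0.2, 1.4) * f1d(q[3], 0.1, 1.4)
  expect_equal(toy_gaussian_structure_factor(m2, q), want, tolerance = 1e-10)
  expect_error(toy_gaussian_model(c(0, 0, 0), -1, 1), "positive")
})

test_that("toy one-Gaussian density agrees with the AO-pair machinery", {
  # a single normalized s AO with exponent a has |chi|^2 = Gaussian(2a);
  # P = w makes the matrix route equal the closed-form toy route
  a <- 0.7; w <- 2
  mol <- molecule(2L, matrix(0, 1, 3))
  refs <- generate_reflection_set(unit_cell(10), 0.2)
  sh <- list(list(l = 0L, center = c(0, 0, 0), exps = a,
                  coefs = xcwfit:::cpp_prim_norm(a, 0L, 0L, 0L), atom = 1L))
  bs <- structure(list(shells = sh, nbf = 1L, name = "custom", molecule = mol),
                  class = "xcw_basis")
  blocks <- ft_ao_pair_integrals(bs, refs)
  F_mat <- structure_factors_from_density(matrix(w, 1, 1), blocks)
  q_bohr <- as.matrix(refs$hkl[, 1:3]) %*% t(refs$cell$B) / xcwfit:::BOHR_PER_ANGSTROM
  model <- toy_gaussian_model(blocks$shift, 2 * a, w)   # shifted to cell center
  F_toy <- toy_gaussian_structure_factor(model, q_bohr)
  expect_equal(F_mat, F_toy, tolerance = 1e-10)
})

test_that("amplitudes scale with eta and are origin independent", {
  expect_equal(amplitude_set(3 + 4i), 5)
  expect_equal(amplitude_set(c(3 + 4i, 1i), eta = 2), c(10, 2))
  expect_length(amplitude_set(complex(0)), 0)
  expect_error(amplitude_set(1 + 0i, eta = 0), "positive")

  # rigid translation changes phases, never amplitudes (RHF water)
  refs <- generate_reflection_set(unit_cell(10), 0.2)
  w1 <- fixture_geometry("water")
  d1 <- rhf_density(w1, "sto-3g")
  w2 <- molecule(w1$Z, sweep(w1$xyz, 2, c(0.8, -0.5, 0.3), `+`))
  d2 <- rhf_density(w2, "sto-3g")
  F1 <- structure_factors_from_density(d1, ft_ao_pair_integrals(d1$basis, refs))
  F2 <- structure_factors_from_density(d2, ft_ao_pair_integrals(d2$basis, refs))
  # the cell-centering convention makes the whole computation translation
  # invariant: amplitudes (and, with centering, phases) coincide
  expect_equal(Mod(F1), Mod(F2), tolerance = 1e-8)
})

test_that("structure-factor contraction is linear and F(000) counts electrons", {
  h2o <- fixture_geometry("water")
  ints <- compute_integrals(h2o, "sto-3g")
  d <- rhf_density(h2o, "sto-3g", ints = ints)
  M0 <- xcwfit:::cpp_ft_blocks(ints$basis$shells, matrix(0, 1, 3))
  n <- ints$nbf
  S <- matrix(0 + 0i, n, n)
  S[lower.tri(S, diag = TRUE)] <- M0[, 1]
  S <- S + t(S); diag(S) <- diag(S) / 2
  expect_equal(Re(sum(d$P * S)), 10, tolerance = 1e-8)

  refs <- generate_reflection_set(unit_cell(10), 0.2)
  blocks <- ft_ao_pair_integrals(ints$basis, refs)
  P1 <- d$P
  set.seed(7)
  P2 <- crossprod(matrix(rnorm(n * n), n))
  expect_equal(structure_factors_from_density(P1 + P2, blocks),
               structure_factors_from_density(P1, blocks) +
                 structure_factors_from_density(P2, blocks),
               tolerance = 1e-10)
  expect_equal(structure_factors_from_density(matrix(0, n, n), blocks),
               rep(0 + 0i, nrow(refs$hkl)))
})

test_that("correlation signal in amplitudes concentrates at low angle", {
  # |F_corr| - |F_RHF| differences shrink with s and change sign (H2/FCI)
  h2 <- fixture_geometry("H2_test")
  ints <- compute_integrals(h2, "6-31g")
  d_rhf <- rhf_density(h2, "6-31g", ints = ints)
  d_fci <- correlated_density(h2, "6-31g", "FCI", ints = ints)
  refs <- generate_reflection_set(unit_cell(10), 1.2)
  blocks <- ft_ao_pair_integrals(ints$basis, refs)
  dF <- Mod(structure_factors_from_density(d_fci, blocks)) -
    Mod(structure_factors_from_density(d_rhf, blocks))
  s <- refs$hkl$s
  lo <- mean(abs(dF[s < 0.4])); hi <- mean(abs(dF[s > 0.9]))
  expect_gt(lo, 5 * hi)
  expect_true(any(dF > 0) && any(dF < 0))
})
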