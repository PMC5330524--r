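# The electronic-structure backend: Gaussian integrals against independent
# closed forms and exact hydrogenic limits, RHF against the textbook H2
# value, ERIs against a reciprocal-space quadrature identity, and the CI
# engine against explicitly constructed matrices and known limits.

test_that("s-type integrals match independent closed-form formulas", {
  bs <- build_basis(fixture_geometry("H2_test"), "sto-3g")
  ints <- compute_integrals(bs$molecule, bs)
  orc <- oracle_s_matrices(bs$shells, as.numeric(bs$molecule$Z), bs$molecule$xyz)
  expect_equal(ints$S, orc$S, tolerance = 1e-10)
  expect_equal(ints$T, orc$T, tolerance = 1e-10)
  expect_equal(ints$V, orc$V, tolerance = 1e-10)
  for (idx in list(c(1, 1, 1, 1), c(1, 1, 2, 2), c(1, 2, 1, 2), c(1, 1, 1, 2))) {
    expect_equal(ints$eri[idx[1], idx[2], idx[3], idx[4]],
                 oracle_s_eri(bs$shells, idx[1], idx[2], idx[3], idx[4]),
                 tolerance = 1e-10)
  }
})

test_that("one-electron p and d blocks reproduce exact hydrogenic energies", {
  # diagonalizing T+V for one proton in a pure-l even-tempered basis must
  # approach the exact 2p (-1/8) and 3d (-1/18) hydrogen levels
  hyd_spectrum <- function(l, exps) {
    sh <- lapply(exps, function(a) {
      list(l = as.integer(l), center = c(0, 0, 0), exps = a,
           coefs = xcwfit:::cpp_prim_norm(a, as.integer(l), 0L, 0L))
    })
    st <- xcwfit:::cpp_overlap_kinetic(sh)
    V <- xcwfit:::cpp_nuclear(sh, 1, matrix(0, 1, 3))
    h <- st$T + V
    es <- eigen(st$S, symmetric = TRUE)
    X <- es$vectors %*% (1 / sqrt(es$values) * t(es$vectors))
    eigen(t(X) %*% h %*% X, symmetric = TRUE, only.values = TRUE)$values
  }
  exps <- 0.008 * 2.5^(0:13)
  # pure p basis: lowest level is the exact hydrogen 2p
  expect_lt(abs(min(hyd_spectrum(1, exps)) + 0.125), 5e-5)
  # Cartesian d shells span pure d plus an s contaminant (x^2+y^2+z^2), so
  # the exact 3d level appears in the spectrum (not necessarily lowest)
  expect_lt(min(abs(hyd_spectrum(2, exps) + 1 / 18)), 5e-5)
})

test_that("RHF reproduces the textbook H2/STO-3G energy and invariants", {
  h2 <- fixture_geometry("H2_test")
  r <- rhf(h2, "sto-3g")
  expect_equal(r$energy, -1.1167, tolerance = 1e-4)       # literature anchor
  ints <- r$ints
  expect_equal(sum(r$P * ints$S), 2, tolerance = 1e-10)
  expect_equal(r$P %*% ints$S %*% r$P, 2 * r$P, tolerance = 1e-8)
  # translation invariance
  h2b <- molecule(h2$Z, sweep(h2$xyz, 2, c(1.1, -0.4, 2.2), `+`))
  expect_equal(rhf(h2b, "sto-3g")$energy, r$energy, tolerance = 1e-10)
})

test_that("total energies are invariant under rigid rotation (p and d blocks)", {
  w <- fixture_geometry("water")
  e1 <- rhf(w, "6-31gdp")$energy
  th <- 0.61
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  R2 <- matrix(c(1, 0, 0, 0, cos(0.33), -sin(0.33), 0, sin(0.33), cos(0.33)), 3, 3)
  e2 <- rhf(molecule(w$Z, w$xyz %*% R %*% R2), "6-31gdp")$energy
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("higher-l ERIs satisfy the reciprocal-space quadrature identity", {
  # (ab|cd) = integral I_ab(q) conj(I_cd(q)) / (pi q^2) dq, evaluated with
  # the quadrature-verified FT path on a spherical product grid
  shells <- list(
    list(l = 1L, center = c(0, 0, 0), exps = 0.9,
         coefs = xcwfit:::cpp_prim_norm(0.9, 1L, 0L, 0L)),
    list(l = 2L, center = c(0.5, 0.3, -0.2), exps = 1.1,
         coefs = xcwfit:::cpp_prim_norm(1.1, 2L, 0L, 0L)))
  eri <- xcwfit:::cpp_eri(shells)
  nr <- 64; na <- 20; nphi <- 40
  gr <- gauss_legendre(nr, 0, 7)
  gc <- gauss_legendre(na, -1, 1)
  phi <- 2 * pi * (seq_len(nphi) - 0.5) / nphi
  ang <- expand.grid(ct = gc$x, ph = phi)
  st <- sqrt(1 - ang$ct^2)
  dirs <- cbind(st * cos(ang$ph), st * sin(ang$ph), ang$ct)
  wang <- rep(gc$w, nphi) * (2 * pi / nphi)
  qpts <- dirs[rep(seq_len(nrow(dirs)), each = nr), ] * gr$x
  # kernel 1/(pi q^2) cancels the q^2 of the volume element
  wq <- rep(wang, each = nr) * gr$w / pi
  M <- xcwfit:::cpp_ft_blocks(shells, qpts)
  n <- 9
  packpos <- function(i, j) {  # i >= j, 1-based, column-major packed
    (j - 1) * n - (j - 1) * (j - 2) / 2 + (i - j + 1)
  }
  # a handful of integrals including pure d-d blocks
  cases <- list(c(2, 3, 5, 9), c(1, 1, 4, 4), c(3, 3, 6, 8), c(5, 7, 5, 7))
  for (cs in cases) {
    Iab <- M[packpos(max(cs[1], cs[2]), min(cs[1], cs[2])), ]
    Icd <- M[packpos(max(cs[3], cs[4]), min(cs[3], cs[4])), ]
    val <- sum(wq * Re(Iab * Conj(Icd)))
    expect_equal(val, eri[cs[1], cs[2], cs[3], cs[4]], tolerance = 1e-6)
  }
})

test_that("2-electron FCI matches an explicitly constructed CI matrix", {
  h2 <- fixture_geometry("H2_test")
  r <- rhf(h2, "sto-3g")
  mo <- xcwfit:::mo_transform(r$ints, r$C)
  t4 <- mo$eri; hmo <- mo$h
  # independent 3x3 singlet CI: |11|, open-shell singlet, |22|
  h11 <- 2 * hmo[1, 1] + t4[1, 1, 1, 1]
  h22 <- 2 * hmo[2, 2] + t4[2, 2, 2, 2]
  hs <- hmo[1, 1] + hmo[2, 2] + t4[1, 1, 2, 2] + t4[1, 2, 2, 1]
  h1s <- sqrt(2) * (hmo[1, 2] + t4[1, 2, 1, 1])
  h2s <- sqrt(2) * (hmo[1, 2] + t4[1, 2, 2, 2])
  h12 <- t4[1, 2, 1, 2]
  H3 <- matrix(c(h11, h1s, h12, h1s, hs, h2s, h12, h2s, h22), 3, 3)
  e_oracle <- min(eigen(H3, symmetric = TRUE)$values) + r$ints$enuc
  d <- correlated_density(h2, "sto-3g", "FCI")
  expect_equal(d$energy, e_oracle, tolerance = 1e-9)
  # CISD == FCI for 2 electrons, including the density
  d2 <- correlated_density(h2, "sto-3g", "CISD")
  expect_equal(d2$energy, d$energy, tolerance = 1e-9)
  expect_equal(d2$P, d$P, tolerance = 1e-8)
})

test_that("helium CI approaches the s-limit and obeys density invariants", {
  he <- fixture_geometry("He")
  # even-tempered 8s helium basis; FCI energy near the s-limit (~ -2.8790)
  tab <- tempfile(fileext = ".txt")
  exps <- 0.12 * 2.9^(0:7)
  writeLines(c("ATOM He",
               unlist(lapply(exps, function(a) c("S 1", sprintf(" %.10f 1.0", a))))),
             tab)
  d <- correlated_density(he, tab, "FCI")
  expect_equal(d$energy, -2.879, tolerance = 2e-3)
  expect_equal(sum(d$P * d$ints$S), 2, tolerance = 1e-8)
  occ <- eigen(d$ints$S %*% d$P, only.values = TRUE)$values
  expect_true(all(Re(occ) > -1e-8 & Re(occ) < 2 + 1e-8))
})

test_that("CISD lowers the energy variationally on a polyatomic", {
  w <- fixture_geometry("water")
  r <- rhf(w, "sto-3g")
  d <- correlated_density(w, "sto-3g", "CISD")
  expect_lt(d$energy, r$energy - 0.01)
  expect_equal(sum(d$P * d$ints$S), 10, tolerance = 1e-8)
  expect_error(correlated_density(w, "sto-3g", "FCI"), "at most 4 electrons")
})

test_that("DFT stage reports its absence explicitly", {
  expect_error(dft_density(fixture_geometry("H2_test"), "sto-3g", "B3LYP"),
               "not available")
})

test_that("geometry optimization finds the grid-scan minimum for H2", {
  h2 <- molecule(c(1L, 1L), rbind(c(0, 0, -0.6), c(0, 0, 0.6)))
  opt <- optimize_geometry(h2, "sto-3g", "RHF")
  r_opt <- sqrt(sum((opt$xyz[2, ] - opt$xyz[1, ])^2))
  rs <- seq(1.1, 1.8, by = 0.002)
  es <- vapply(rs, function(r) {
    rhf(molecule(c(1L, 1L), rbind(c(0, 0, -r / 2), c(0, 0, r / 2))), "sto-3g")$energy
  }, 0)
  expect_equal(r_opt, rs[which.min(es)], tolerance = 1e-3)
  expect_lt(attr(opt, "max_grad"), 1e-5)
})

test_that("symmetric geometries stay symmetric under optimization", {
  w <- fixture_geometry("water")
  opt <- optimize_geometry(w, "sto-3g", "RHF", maxit = 60L)
  r1 <- sqrt(sum((opt$xyz[2, ] - opt$xyz[1, ])^2))
  r2 <- sqrt(sum((opt$xyz[3, ] - opt$xyz[1, ])^2))
  expect_equal(r1, r2, tolerance = 1e-6)
})
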