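# Real-space metric suite: grid densities, BCP search, similarity indices.

make_field <- function(values, grid) {
  structure(list(grid = grid, values = values, molecule = NULL,
                 nelec_grid = sum(values) * grid$voxel, method = "synthetic"),
            class = "xcw_field")
}

test_that("grid densities normalize and match pointwise AO evaluation", {
  h2 <- h2_fixture()
  d <- rhf_density(h2, "sto-3g")
  grid <- default_grid(h2, spacing = 0.2)
  f <- density_on_grid(d, grid)
  expect_equal(f$nelec_grid, 2, tolerance = 0.005 * 2)
  # maximum sits at/near a nucleus
  pts <- xcwfit:::grid_points(grid)
  imax <- which.max(f$values)
  expect_lt(min(sqrt(colSums((t(h2$xyz) - pts[imax, ])^2))), 0.3)
  # pointwise oracle: independent s/p AO evaluation at 10 random points
  w <- fixture_geometry("water")
  dw <- rhf_density(w, "sto-3g")
  set.seed(3)
  rp <- matrix(rnorm(30, sd = 1.2), 10, 3)
  ao <- oracle_ao_values(dw$basis$shells, rp)
  want <- rowSums((ao %*% dw$P) * ao)
  aop <- xcwfit:::cpp_ao_values(dw$basis$shells, rp)
  got <- rowSums((aop %*% dw$P) * aop)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("analytic density derivatives match central differences", {
  w <- fixture_geometry("water")
  d <- rhf_density(w, "sto-3g")
  set.seed(5)
  for (k in 1:3) {
    x <- rnorm(3, sd = 0.8)
    gh <- rho_grad_hess(d, x)
    expect_equal(gh$hessian, t(gh$hessian))
    h <- 1e-4
    for (i in 1:3) {
      e <- numeric(3); e[i] <- h
      fp <- rho_grad_hess(d, x + e)$rho
      fm <- rho_grad_hess(d, x - e)$rho
      expect_equal(gh$grad[i], (fp - fm) / (2 * h), tolerance = 1e-6)
      expect_equal(gh$hessian[i, i],
                   (fp - 2 * gh$rho + fm) / h^2, tolerance = 1e-4)
    }
  }
  # symmetry: H2 midpoint has a vanishing gradient
  h2 <- h2_fixture()
  dh <- rhf_density(h2, "sto-3g")
  expect_lt(max(abs(rho_grad_hess(dh, c(0, 0, 0))$grad)), 1e-12)
})

test_that("BCP search finds the midpoint of homonuclear diatomics", {
  h2 <- h2_fixture()
  d <- rhf_density(h2, "6-31g")
  cp <- find_bcp(d, 1, 2)
  expect_equal(cp$position, c(0, 0, 0), tolerance = 1e-6)
  expect_equal(cp$signature[2], -1)
  expect_lt(cp$grad_norm, 1e-8)
  # 1-D scan oracle: rho at the BCP equals the minimum along the bond axis
  zs <- seq(-0.5, 0.5, by = 1e-3)
  rhos <- vapply(zs, function(z) rho_grad_hess(d, c(0, 0, z))$rho, 0)
  expect_equal(cp$rho, min(rhos), tolerance = 1e-6)
})

test_that("water O-H bond critical point lies near the bond axis", {
  w <- fixture_geometry("water")
  d <- rhf_density(w, "sto-3g")
  cp <- find_bcp(d, 1, 2)
  expect_equal(cp$signature[2], -1)
  a <- w$xyz[1, ]; b <- w$xyz[2, ]
  t_ <- sum((cp$position - a) * (b - a)) / sum((b - a)^2)
  perp <- cp$position - (a + t_ * (b - a))
  expect_gt(t_, 0.3); expect_lt(t_, 0.95)
  expect_lt(sqrt(sum(perp^2)), 0.1)
})

test_that("the topological index is the linear placement between benchmarks", {
  expect_equal(topological_index(0.30, 0.35, 0.30), 0)
  expect_equal(topological_index(0.35, 0.35, 0.30), 100)
  expect_equal(topological_index(0.325, 0.35, 0.30), 50)
  expect_error(topological_index(0.3, 0.31, 0.31), "degenerate")
})

test_that("RSR obeys its closed-form cases", {
  g <- grid_spec(c(0, 0, 0), 0.5, c(4, 4, 4))
  v <- runif(64) + 0.1
  f1 <- make_field(v, g)
  expect_equal(rsr(f1, f1), 0)
  expect_equal(rsr(make_field(2 * v, g), f1), 1 / 3)
  v2 <- rep(0, 64); v2[1:32] <- 1
  v3 <- rep(0, 64); v3[33:64] <- 1
  expect_equal(rsr(make_field(v2, g), make_field(v3, g)), 1)
  expect_error(rsr(f1, make_field(v[1:27], grid_spec(c(0, 0, 0), 0.5, c(3, 3, 3)))),
               "different grids")
})

test_that("Carbo distance matches the analytic Gaussian-product integral", {
  g <- grid_spec(c(-6, -6, -6), 0.2, c(61, 61, 61))
  pts <- xcwfit:::grid_points(g)
  gauss <- function(c0, a) a^1.5 / pi^1.5 * exp(-a * rowSums(sweep(pts, 2, c0)^2))
  fA <- make_field(gauss(c(-0.4, 0, 0.2), 1.1), g)
  fB <- make_field(gauss(c(0.5, -0.1, 0), 0.8), g)
  expect_equal(carbo_distance(fA, fA), 0)
  # analytic Z_AB for two normalized Gaussians
  zab_exact <- function(a, b, d2) (a * b / (pi * (a + b)))^1.5 * exp(-a * b / (a + b) * d2)
  d2 <- sum((c(-0.4, 0, 0.2) - c(0.5, -0.1, 0))^2)
  expect_equal(carbo_overlap(fA, fB), zab_exact(1.1, 0.8, d2), tolerance = 1e-6)
  want <- sqrt(zab_exact(1.1, 1.1, 0) + zab_exact(0.8, 0.8, 0) - 2 * zab_exact(1.1, 0.8, d2))
  expect_equal(carbo_distance(fA, fB), want, tolerance = 1e-5)
  # disjoint supports: d = sqrt(Z_II + Z_JJ)
  v2 <- rep(0, prod(g$npts)); v2[1:100] <- 0.3
  v3 <- rep(0, prod(g$npts)); v3[101:200] <- 0.4
  f2 <- make_field(v2, g); f3 <- make_field(v3, g)
  expect_equal(carbo_distance(f2, f3),
               sqrt(carbo_overlap(f2, f2) + carbo_overlap(f3, f3)))
})

test_that("RMSD and MAD follow their definitions", {
  g <- grid_spec(c(0, 0, 0), 1, c(2, 2, 2))
  v <- runif(8)
  f <- make_field(v, g)
  expect_equal(rmsd_mad(f, f), c(rmsd = 0, mad = 0))
  expect_equal(rmsd_mad(make_field(v + 0.3, g), f), c(rmsd = 0.3, mad = 0.3))
  f0 <- make_field(c(0, 0, rep(0, 6)), g)
  f2 <- make_field(c(0, 2, rep(0, 6)), g)
  rm_ <- rmsd_mad(f0, f2)
  expect_equal(rm_[["rmsd"]], sqrt(4 / 8))
  expect_equal(rm_[["mad"]], 2 / 8)
  expect_gte(rm_[["rmsd"]], rm_[["mad"]])
})

test_that("bond profiles are symmetric for H2 and hit the endpoints", {
  h2 <- h2_fixture()
  d <- rhf_density(h2, "6-31g")
  pr <- bond_profile(d, h2$xyz[1, ], h2$xyz[2, ], 101)
  expect_equal(pr$rho, rev(pr$rho), tolerance = 1e-10)
  p2 <- bond_profile(d, h2$xyz[1, ], h2$xyz[2, ], 2)
  expect_equal(nrow(p2), 2)
  expect_equal(p2$rho[1], rho_grad_hess(d, h2$xyz[1, ])$rho, tolerance = 1e-12)
  # RHF minus FCI is positive at the bond midpoint (minimal basis)
  dF <- correlated_density(h2, "sto-3g", "FCI")
  dR <- rhf_density(h2, "sto-3g")
  mid_R <- bond_profile(dR, h2$xyz[1, ], h2$xyz[2, ], 3)$rho[2]
  mid_F <- bond_profile(dF, h2$xyz[1, ], h2$xyz[2, ], 3)$rho[2]
  expect_gt(mid_R, mid_F)
})

test_that("grid-based indicators converge with spacing (Richardson check)", {
  h2 <- h2_fixture()
  dR <- rhf_density(h2, "6-31g")
  dF <- correlated_density(h2, "6-31g", "FCI")
  vals <- vapply(c(0.4, 0.2, 0.1), function(sp) {
    g <- default_grid(h2, spacing = sp, margin = 4)
    rsr(density_on_grid(dR, g), density_on_grid(dF, g))
  }, 0)
  expect_lt(abs(vals[3] - vals[2]), abs(vals[2] - vals[1]))
  # sensitivity of the default spacing: 0.15 vs 0.10 changes RSR only a little
  g15 <- default_grid(h2, spacing = 0.15, margin = 4)
  g10 <- default_grid(h2, spacing = 0.10, margin = 4)
  r15 <- rsr(density_on_grid(dR, g15), density_on_grid(dF, g15))
  r10 <- rsr(density_on_grid(dR, g10), density_on_grid(dF, g10))
  expect_lt(abs(r15 - r10) / r10, 0.05)
})

test_that("all indicators vanish when a density is compared with itself", {
  h2 <- h2_fixture()
  d <- rhf_density(h2, "sto-3g")
  rep_ <- similarity_report(d, d, correlated_density(h2, "sto-3g", "FCI"),
                            bonds = fixture_bonds("H2_test"),
                            grid = default_grid(h2, spacing = 0.25, margin = 4))
  expect_equal(unname(rep_$ti), 100)   # the model here IS the RHF benchmark
  d2 <- correlated_density(h2, "sto-3g", "FCI")
  rep2 <- similarity_report(d2, d, d2, bonds = fixture_bonds("H2_test"),
                            grid = default_grid(h2, spacing = 0.25, margin = 4))
  expect_equal(unname(rep2$ti), 0, tolerance = 1e-6)
  expect_equal(rep2$rsr, 0, tolerance = 1e-12)
  expect_equal(rep2$carbo, 0, tolerance = 1e-8)
  expect_equal(rep2$rmsd, 0, tolerance = 1e-12)
})
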