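# Energy kernels: LJ closed forms, Ewald vs direct sum, periodicity,
# lambda coupling.

lj_pair_system <- function(r, epsilon = 1, sigma = 0.3, L = 5, rc = 2,
                           tail = FALSE) {
  sp <- lj_species("LJ", epsilon = epsilon, sigma = sigma)
  ff <- ff_bundle(list(sp), rc = rc, tail = tail)
  st <- build_system(ff, c(LJ = 2), L = L, seed = 1)
  st <- place_points(st, rbind(c(1, 1, 1), c(1 + r, 1, 1)))
  list(ff = ff, st = st)
}

test_that("LJ closed forms: zero at sigma, -epsilon at the minimum", {
  s <- lj_pair_system(0.3)
  expect_equal(total_energy(s$st, s$ff), 0, tolerance = 1e-12)
  s <- lj_pair_system(0.3 * 2^(1 / 6))
  expect_equal(total_energy(s$st, s$ff), -1, tolerance = 1e-12)
  # hard overlap is +Inf, not an error
  s <- lj_pair_system(0)
  expect_identical(total_energy(s$st, s$ff), Inf)
})

test_that("LJ tail correction matches the analytic homogeneous expression", {
  N <- 20; L <- 2.2; eps <- 0.6; sig <- 0.34; rc <- 0.9
  sp <- lj_species("LJ", epsilon = eps, sigma = sig)
  ff_no <- ff_bundle(list(sp), rc = rc, tail = FALSE)
  ff_yes <- ff_bundle(list(sp), rc = rc, tail = TRUE)
  st <- build_system(ff_no, c(LJ = N), L = L, seed = 4)
  sr3 <- (sig / rc)^3
  expected <- N^2 / (2 * L^3) * (16 * pi / 3) * eps * sig^3 *
    (sr3^3 / 3 - sr3)
  expect_equal(total_energy(st, ff_yes) - total_energy(st, ff_no),
               expected, tolerance = 1e-10)
})

test_that("energy is invariant under translation by a lattice vector", {
  ff <- ff_bundle(list(water_tip4p2005()), rc = 0.45)
  st <- build_system(ff, c(H2O = 12), rho_mass = 997, seed = 8)
  e0 <- total_energy(st, ff)
  for (shift in list(c(st$L, 0, 0), c(0, -st$L, 0), c(2 * st$L, st$L, -st$L))) {
    st2 <- st
    st2$com <- sweep(st$com, 2L, shift, "+")
    expect_lt(abs(total_energy(st2, ff) - e0), 1e-8)
  }
  # deterministic: identical input gives identical output
  expect_identical(total_energy(st, ff), e0)
})

test_that("Ewald matches the shell-summed direct Coulomb oracle", {
  # dipole-free fixtures (8 charges) so the spherical shell sum converges
  # to the tinfoil limit the Ewald sum computes
  L <- 2.0
  spp <- lj_species("Qp", epsilon = 0, sigma = 0, charge = 1, mass = 1)
  spm <- lj_species("Qm", epsilon = 0, sigma = 0, charge = -1, mass = 1)
  ff <- ff_bundle(list(spp, spm), rc = 0.9, tail = FALSE,
                  ewald_accuracy = 1e-6)
  for (seed in c(7, 19)) {
    cfg <- dipole_free_config(2, L = L, seed = seed)
    ord <- order(cfg$q, decreasing = TRUE)
    st <- build_system(ff, c(Qp = 4, Qm = 4), L = L, seed = 1)
    st <- place_points(st, cfg$pos[ord, ])
    e_ew <- total_energy(st, ff)
    cum <- direct_coulomb_energy(cfg$pos[ord, ], cfg$q[ord], L, nshell = 16)
    e_dir <- direct_coulomb_extrapolate(cum)
    scatter <- diff(range(utils::tail(cum, 4)))
    expect_lt(abs(e_ew - e_dir), max(1e-5 * abs(e_dir), 3 * scatter))
  }
})

test_that("the rock-salt lattice recovers the Madelung constant", {
  fx <- make_fixture("charge_lattice", list(ncell = 2L, d = 0.4))
  e_pair <- total_energy(fx$state, fx$ff) / fx$n_pairs
  expect_equal(e_pair, fx$expected$energy_per_pair, tolerance = 1e-4)
  # back out the dimensionless constant
  M <- -e_pair * fx$d / ecs_constants()$ke
  expect_equal(M, 1.747565, tolerance = 1e-4)
})

test_that("lambda coupling is zero at 0, exact at 1, finite at overlap", {
  ff <- ff_bundle(list(water_tip4p2005()), rc = 0.45)
  st <- build_system(ff, c(H2O = 10), rho_mass = 997, frac = c(H2O = 1),
                     frac_surface = "ECS", seed = 5)
  expect_identical(lambda_coupled_energy(st, 0, ff), 0)
  st1 <- st; st1$lambda <- 1
  st0 <- st; st0$lambda <- 0
  full_group <- total_energy(st1, ff) - total_energy(st0, ff)
  expect_equal(lambda_coupled_energy(st, 1, ff), full_group,
               tolerance = 1e-9)
  # continuity: small lambda gives small coupling energy
  expect_lt(abs(lambda_coupled_energy(st, 1e-6, ff)), 1e-2)
  # overlap: put the fractional molecule on top of a host molecule
  st_ov <- st
  st_ov$com[st$frac, ] <- st$com[1, ]
  expect_true(is.finite(lambda_coupled_energy(st_ov, 0.3, ff)))
  expect_false(is.finite(lambda_coupled_energy(st_ov, 1, ff)))
  expect_error(lambda_coupled_energy(st, 1.2, ff), "lambda")
  expect_error(lambda_coupled_energy(st, -0.1, ff), "lambda")
})

test_that("PES and ECS fractional surfaces differ only through the charges", {
  ff <- ff_bundle(list(water_tip4p2005()), rc = 0.45)
  stp <- build_system(ff, c(H2O = 10), rho_mass = 997, frac = c(H2O = 1),
                      frac_surface = "PES", seed = 5)
  ste <- stp; ste$frac_surface <- "ECS"
  # at lambda = 0.5 charges are off: both surfaces give identical coupling
  expect_equal(lambda_coupled_energy(stp, 0.5, ff),
               lambda_coupled_energy(ste, 0.5, ff), tolerance = 1e-12)
  # at lambda = 1 they differ (electrostatics on)
  expect_false(isTRUE(all.equal(lambda_coupled_energy(stp, 1, ff),
                                lambda_coupled_energy(ste, 1, ff))))
})
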