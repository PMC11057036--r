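# Sampling correctness of the NPT CFCMC engine.

test_that("runs are reproducible given the seed", {
  fx <- make_fixture("lj_fluid", list(Tstar = 1.5, rhostar = 0.2, N = 16))
  ens <- ensemble_spec(300, 1, move_weights = c(0.8, 0, 0.2, 0, 0))
  r1 <- run_npt(fx$ff, fx$state, ens, nsteps_equil = 5e3, nsteps_prod = 2e4,
                nblocks = 4, seed = 123)
  r2 <- run_npt(fx$ff, fx$state, ens, nsteps_equil = 5e3, nsteps_prod = 2e4,
                nblocks = 4, seed = 123)
  expect_identical(r1$final_state$com, r2$final_state$com)
  expect_identical(r1$density$blocks, r2$density$blocks)
  expect_identical(r1$u$blocks, r2$u$blocks)
  r3 <- run_npt(fx$ff, fx$state, ens, nsteps_equil = 5e3, nsteps_prod = 2e4,
                nblocks = 4, seed = 124)
  expect_false(identical(r1$final_state$com, r3$final_state$com))
  # seed is mandatory
  expect_error(run_npt(fx$ff, fx$state, ens, 10, 10), "seed")
})

test_that("null moves are always accepted and overlaps always rejected", {
  expect_equal(metropolis_probability(0, 300), 1)
  expect_equal(metropolis_probability(-5, 300), 1)
  expect_equal(metropolis_probability(Inf, 300), 0)
  kT <- kBT(300)
  expect_equal(metropolis_probability(kT, 300), exp(-1))
  expect_equal(metropolis_probability(kT, 300, delta_bias = 1), 1)
})

test_that("ideal-gas NPT sampling obeys the density law", {
  fx <- make_fixture("ideal_gas", list(N = 30, T = 300, P = 1))
  ens <- ensemble_spec(300, 1, move_weights = c(0.9, 0, 0.1, 0, 0))
  run <- run_npt(fx$ff, fx$state, ens, nsteps_equil = 2e4,
                 nsteps_prod = 2e5, nblocks = 5, seed = 7)
  z <- (run$density$mean - fx$expected$density) / run$density$se
  expect_lt(abs(z), 3)
  expect_identical(run$u$mean, 0)   # no interactions at all
})

test_that("two-particle pair distances follow the Boltzmann distribution", {
  # NVT sampling of two LJ particles; compare the sampled minimum-image
  # distance density on r < L/2 against direct quadrature of
  # r^2 exp(-u(r)/kBT)
  T <- 300; eps <- kBT(300); sig <- 0.3; L <- 1.2; rc <- 0.55
  sp <- lj_species("LJ", epsilon = eps, sigma = sig)
  ff <- ff_bundle(list(sp), rc = rc, tail = FALSE)
  st <- build_system(ff, c(LJ = 2), L = L, seed = 2)
  ens <- ensemble_spec(T, 1, move_weights = c(1, 0, 0, 0, 0), dmax = 0.15)
  run <- run_npt(ff, st, ens, nsteps_equil = 2e4, nsteps_prod = 1.2e6,
                 nblocks = 5, seed = 31, sample_every = 5,
                 sample_pair = TRUE)
  r <- run$pair_dist
  r <- r[r < L / 2]
  edges <- seq(0.24, L / 2, length.out = 9)
  obs <- as.vector(table(cut(r, edges))) / length(r)
  pexp <- vapply(seq_len(8), function(i) {
    stats::integrate(function(x)
      lj_pair_dist_oracle(x, L, eps, sig, T, rc), edges[i], edges[i + 1],
      rel.tol = 1e-8)$value
  }, numeric(1))
  # renormalize both to the window and compare bin probabilities
  pexp <- pexp / sum(pexp)
  obs <- obs / sum(obs)
  se <- sqrt(pexp * (1 - pexp) / length(r))
  # distances are serially correlated; allow an effective-sample inflation
  zmax <- max(abs(obs - pexp) / (se * sqrt(10)))
  expect_lt(zmax, 4)
})

test_that("a non-interacting fractional group has zero excess chemical potential", {
  sp <- lj_species("IG", epsilon = 0, sigma = 0, mass = 40)
  ff <- ff_bundle(list(sp), rc = 0.9, tail = FALSE)
  st <- build_system(ff, c(IG = 20), L = 3, frac = c(IG = 1), seed = 3)
  ens <- ensemble_spec(300, 1, move_weights = c(0.3, 0, 0, 0.5, 0.2),
                       nbins = 21)
  run <- run_npt(ff, st, ens, nsteps_equil = 3e5, nsteps_prod = 6e5,
                 nblocks = 10, seed = 5)
  expect_true(run$wl_converged)
  mu <- estimate_mu_ex(run$lambda_histogram, 300)
  expect_lt(abs(mu$value), 3 * max(mu$std_error, 0.02))
  # converged bias weights are flat for a flat landscape
  eta <- run$lambda_histogram$eta
  expect_lt(diff(range(eta)), 0.5)
})

test_that("Widom insertion into an ideal gas gives exactly zero", {
  sp <- lj_species("IG", epsilon = 0, sigma = 0, mass = 40)
  ff <- ff_bundle(list(sp), rc = 0.9, tail = FALSE)
  st <- build_system(ff, c(IG = 10), L = 3, seed = 3)
  ens <- ensemble_spec(300, 1, move_weights = c(0.9, 0, 0.1, 0, 0))
  run <- run_npt(ff, st, ens, nsteps_equil = 1e3, nsteps_prod = 2e4,
                 nblocks = 4, seed = 17, widom_species = "IG",
                 widom_every = 10, widom_n = 2)
  expect_equal(widom_mu_ex(run)$value, 0, tolerance = 1e-12)
})

test_that("Widom mu_ex is positive and monotone in density for a dense repulsive fluid", {
  # T* = 5: repulsion dominates, so mu_ex is positive and grows with density
  sp <- lj_species("LJ", epsilon = kBT(300) / 5, sigma = 0.3)
  ff <- ff_bundle(list(sp), rc = 0.75, tail = FALSE)
  mus <- vapply(c(0.5, 0.85), function(rhostar) {
    L <- (24 * 0.3^3 / rhostar)^(1 / 3)
    st <- build_system(ff, c(LJ = 24), L = L, seed = 6)
    ens <- ensemble_spec(300, 1, move_weights = c(1, 0, 0, 0, 0),
                         dmax = 0.05)
    run <- run_npt(ff, st, ens, nsteps_equil = 4e4, nsteps_prod = 1.5e5,
                   nblocks = 4, seed = 19, widom_species = "LJ",
                   widom_every = 10, widom_n = 5)
    widom_mu_ex(run)$value
  }, numeric(1))
  expect_gt(mus[2], mus[1])
  expect_gt(mus[2], 0)
})

test_that("CFCMC and Widom agree on a dilute LJ fluid", {
  # same host (31 particles) and volume for both estimators, so they
  # measure the same insertion free energy
  fx <- make_fixture("lj_fluid", list(Tstar = 1.5, rhostar = 0.25, N = 32))
  ff <- fx$ff
  L <- fx$state$L
  sth <- build_system(ff, c(LJ = 31), L = L, seed = 2)
  ens_w <- ensemble_spec(300, 1, move_weights = c(1, 0, 0, 0, 0))
  rw <- run_npt(ff, sth, ens_w, nsteps_equil = 1e5, nsteps_prod = 8e5,
                nblocks = 10, seed = 21, widom_species = "LJ",
                widom_every = 10, widom_n = 5)
  mu_w <- widom_mu_ex(rw)
  stc <- build_system(ff, c(LJ = 32), L = L, frac = c(LJ = 1), seed = 2)
  ens_c <- ensemble_spec(300, 1, move_weights = c(0.4, 0, 0, 0.4, 0.2),
                         nbins = 21)
  rc_run <- run_npt(ff, stc, ens_c, nsteps_equil = 4e5, nsteps_prod = 2e6,
                    nblocks = 10, seed = 42)
  expect_true(rc_run$wl_converged)
  mu_c <- estimate_mu_ex(rc_run$lambda_histogram, 300,
                         tail_mu = rc_run$tail_mu_frac)
  comb <- sqrt(mu_c$std_error^2 + mu_w$std_error^2)
  expect_lt(abs(mu_c$value - mu_w$value), 2 * comb)
  # and the dilute-limit virial estimate is in the right neighbourhood
  expect_lt(abs(mu_w$value - fx$expected$mu_ex_dilute),
            0.35 * abs(fx$expected$mu_ex_dilute))
})

test_that("Widom tracks the virial limit at low density", {
  # at rho* = 0.05 the second-virial form holds up to O(rho^2) corrections
  fx <- make_fixture("lj_fluid", list(Tstar = 1.5, rhostar = 0.05, N = 32))
  ens <- ensemble_spec(300, 1, move_weights = c(1, 0, 0, 0, 0))
  run <- run_npt(fx$ff, fx$state, ens, nsteps_equil = 1e5,
                 nsteps_prod = 6e5, nblocks = 8, seed = 9,
                 widom_species = "LJ", widom_every = 10, widom_n = 4)
  w <- widom_mu_ex(run)
  expect_equal(w$value, fx$expected$mu_ex_dilute, tolerance = 0.08)
})

test_that("the Wang-Landau toy recovers two-state weight differences", {
  for (r in c(3, 10)) {
    fx <- make_fixture("two_state", list(r = r))
    h <- wl_sample_discrete(fx$probs, seed = 11)
    expect_true(h$converged)
    expect_equal(h$eta[1] - h$eta[2], fx$expected$delta_eta,
                 tolerance = 0.15)
  }
  # gauge invariance: scaling all probabilities leaves differences intact
  h1 <- wl_sample_discrete(c(0.25, 0.75), seed = 4)
  h2 <- wl_sample_discrete(c(1, 3), seed = 4)
  expect_equal(h1$eta[1] - h1$eta[2], h2$eta[1] - h2$eta[2],
               tolerance = 1e-12)
})

test_that("bias schedule halves the factor on flat histograms only", {
  h <- lambda_histogram(nbins = 4, f = 1)
  for (b in c(1, 2, 3, 4, 1, 2, 3, 4)) h <- wl_visit(h, b)
  h2 <- update_bias(h)
  expect_equal(h2$f, 0.5)
  expect_equal(sum(h2$counts), 0)
  # strongly peaked histogram: no update
  h3 <- lambda_histogram(nbins = 4, f = 1)
  for (b in c(1, 1, 1, 1, 1, 2)) h3 <- wl_visit(h3, b)
  expect_equal(update_bias(h3)$f, 1)
})

test_that("mu_ex estimation demands sampled terminal bins", {
  h <- lambda_histogram(nbins = 5)
  h$counts <- c(0, 3, 5, 2, 1)
  expect_error(estimate_mu_ex(h, 300), "insufficient")
})

test_that("mc_step advances a state deterministically", {
  fx <- make_fixture("lj_fluid", list(Tstar = 1.5, rhostar = 0.2, N = 8))
  ens <- ensemble_spec(300, 1, move_weights = c(1, 0, 0, 0, 0))
  s1 <- mc_step(fx$state, ens, fx$ff, seed = 99)
  s2 <- mc_step(fx$state, ens, fx$ff, seed = 99)
  expect_identical(s1$com, s2$com)
  expect_s3_class(s1, "system_state")
})
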