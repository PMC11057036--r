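# Free-energy corrections, fits, activities and hydration records.

test_that("epsilon correction subtracts surfaces and propagates errors", {
  mu_e <- mu_ex_estimate(-26.37, 0.10, "ECS", T = 300, P = 1)
  mu_p <- mu_ex_estimate(-30.00, 0.10, "PES", T = 300, P = 1)
  e <- epsilon_correction(mu_e, mu_p)
  expect_equal(e$epsilon, 3.63)
  expect_equal(e$std_error, sqrt(0.02), tolerance = 1e-12)
  expect_equal(e$T, 300)
  # identical surfaces give zero
  z <- epsilon_correction(mu_ex_estimate(-30, 0, "ECS", T = 300, P = 1),
                          mu_ex_estimate(-30, 0, "PES", T = 300, P = 1))
  expect_equal(z$epsilon, 0)
  # mismatched state points rejected
  expect_error(epsilon_correction(
    mu_ex_estimate(-26, 0, "ECS", T = 300, P = 1),
    mu_ex_estimate(-30, 0, "PES", T = 350, P = 1)), "inconsistent")
  expect_error(epsilon_correction(
    mu_ex_estimate(-26, 0, "ECS", T = 300, P = 1, molality = 1),
    mu_ex_estimate(-30, 0, "PES", T = 300, P = 1, molality = 1)),
    "molality")
  expect_error(epsilon_correction(mu_p, mu_e), "tagged")
})

test_that("the published linear fit evaluates consistently", {
  fit <- list(A0 = 5.00, A1 = -4.36e-3)
  expect_equal(epsilon_at(fit, 350), 5.00 - 4.36e-3 * 350)
  expect_equal(epsilon_at(fit, 350), 3.474)
})

test_that("linear epsilon fit is exact on collinear data and errors on degenerate input", {
  pts <- data.frame(T = c(300, 400), epsilon = c(2.0, 1.2))
  fit <- fit_epsilon_linear(pts)
  expect_equal(fit$A1, (1.2 - 2.0) / 100)
  expect_equal(fit$A0, 2.0 - fit$A1 * 300)
  expect_equal(max(abs(fit$residuals$residual)), 0, tolerance = 1e-12)
  expect_error(fit_epsilon_linear(pts[1, ]), "degenerate")
  expect_error(fit_epsilon_linear(
    data.frame(T = c(300, 300), epsilon = c(1, 2))), "degenerate")
})

test_that("noisy synthetic epsilon tables are recovered without bias", {
  # 1000 replicates of Gaussian noise sigma = 0.05 on 5 temperatures:
  # the mean recovered A0 must sit within 3 standard errors of the truth
  A0 <- 5.00; A1 <- -4.36e-3
  Ts <- c(300, 350, 400, 450, 500)
  nrep <- 1000
  a0s <- numeric(nrep)
  a1s <- numeric(nrep)
  set.seed(2024)
  X <- cbind(1, Ts)
  for (r in seq_len(nrep)) {
    eps <- A0 + A1 * Ts + rnorm(5, 0, 0.05)
    co <- stats::lm.fit(X, eps)$coefficients
    a0s[r] <- co[1]; a1s[r] <- co[2]
  }
  expect_lt(abs(mean(a0s) - A0), 3 * sd(a0s) / sqrt(nrep))
  expect_lt(abs(mean(a1s) - A1), 3 * sd(a1s) / sqrt(nrep))
  # the package fit agrees with the direct normal-equation oracle
  tab <- data.frame(T = Ts, epsilon = A0 + A1 * Ts + rnorm(5, 0, 0.05))
  fit <- fit_epsilon_linear(tab)
  co <- stats::lm.fit(X, tab$epsilon)$coefficients
  expect_equal(fit$A0, unname(co[1]))
  expect_equal(fit$A1, unname(co[2]))
})

test_that("weighted epsilon fit uses reported uncertainties", {
  tab <- data.frame(T = c(300, 400, 500), epsilon = c(3.7, 3.3, 2.0),
                    sigma = c(0.01, 0.01, 10))
  wfit <- fit_epsilon_linear(tab, weighted = TRUE)
  # the wild third point is downweighted: fit follows the first two
  expect_equal(wfit$A1, (3.3 - 3.7) / 100, tolerance = 1e-3)
  expect_error(fit_epsilon_linear(tab[, 1:2], weighted = TRUE), "sigma")
})

test_that("corrected chemical potential is purely additive", {
  r <- corrected_mu(-10.0, -30.0, 3.69)
  expect_equal(r$mu_total, -36.31)
  expect_equal(corrected_mu(1, 2, 0)$mu_total, 3)
  # additivity in the correction
  a <- corrected_mu(-8.2, -29.1, 0)$mu_total
  expect_equal(corrected_mu(-8.2, -29.1, 2.5)$mu_total, a + 2.5)
  # accepts an epsilon_correction object
  e <- epsilon_correction(mu_ex_estimate(-26.37, 0, "ECS", T = 300, P = 1),
                          mu_ex_estimate(-30.00, 0, "PES", T = 300, P = 1))
  expect_equal(corrected_mu(-10, -30, e)$mu_total, -10 - 30 + 3.63)
})

test_that("water activity closed forms and epsilon cancellation hold", {
  # identical state points: a_w = 1
  expect_equal(water_activity(-30, -30, 1.0, 1.0, 300)$a_w, 1)
  # density ratio alone
  expect_equal(water_activity(-30, -30, 0.9, 1.0, 300, molality = 1)$a_w, 0.9)
  # Boltzmann factor alone
  kT <- kBT(300)
  expect_equal(
    water_activity(-30 - kT * log(2), -30, 1, 1, 300, molality = 1)$a_w, 0.5)
  # epsilon cancellation: any common shift leaves a_w unchanged exactly
  base <- water_activity(-31.4, -30.0, 0.93, 1.0, 298, molality = 3)
  for (delta in c(3.63, -5, 0.01)) {
    shifted <- water_activity(-31.4 + delta, -30.0 + delta, 0.93, 1.0, 298,
                              molality = 3)
    expect_identical(shifted$a_w, base$a_w)
  }
  # mole fraction with full dissociation, NaCl at 2 mol/kg
  ar <- water_activity(-30, -30, 1, 1, 298, molality = 2, nu_ions = 2)
  expect_equal(ar$x_w, (1000 / 18.015) / (1000 / 18.015 + 4))
  expect_equal(ar$gamma_w, ar$a_w / ar$x_w)
  expect_error(water_activity(-30, -30, -1, 1, 300), "positive")
})

test_that("hydration normalization divides by the integer cation charge", {
  expect_equal(normalized_hydration(-700, 1)$mu_ex_per_zc, -700)
  expect_equal(normalized_hydration(-1600, 2)$mu_ex_per_zc, -800)
  expect_error(normalized_hydration(-700, 3), "unsupported")
})

test_that("heat of vaporization follows -u + RT and the ECS enthalpy shift", {
  R <- ecs_constants()$kB
  expect_equal(heat_of_vaporization(0, 298.15), R * 298.15)
  expect_equal(heat_of_vaporization(0, 298.15), 2.479, tolerance = 1e-4)
  # linearity in T at fixed u
  u <- -47.7
  expect_equal(heat_of_vaporization(u, 350) - heat_of_vaporization(u, 300),
               R * 50)
  # for a linear eps(T) the enthalpy correction is exactly A0
  fit <- list(A0 = 5.00, A1 = -4.36e-3)
  expect_equal(heat_of_vaporization(u, 298.15) -
                 heat_of_vaporization_ecs(u, 298.15, fit), 5.00)
})
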