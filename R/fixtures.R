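# Deterministic test fixtures with analytically known expectations.

#' Second virial coefficient of the Lennard-Jones fluid
#'
#' B2(T) = -2 pi Int (exp(-u(r)/kBT) - 1) r^2 dr by adaptive quadrature
#' over the full (untruncated) potential. In the dilute limit the excess
#' chemical potential approaches 2 B2 rho k_B T.
#'
#' @param T temperature, K
#' @param epsilon LJ well depth, kJ/mol
#' @param sigma LJ diameter, nm
#' @return B2 in nm^3
#' @export
lj_b2 <- function(T, epsilon = 1, sigma = 0.3) {
  beta <- 1 / kBT(T)
  f <- function(r) {
    u <- 4 * epsilon * ((sigma / r)^12 - (sigma / r)^6)
    (exp(-pmin(beta * u, 700)) - 1) * r^2
  }
  # integrand is -r^2 below ~0.8 sigma; split for the quadrature
  i1 <- stats::integrate(f, 0, 0.8 * sigma, rel.tol = 1e-10)$value
  i2 <- stats::integrate(f, 0.8 * sigma, 20 * sigma, rel.tol = 1e-10)$value
  -2 * pi * (i1 + i2)
}

#' Build a named test fixture with attached expected values
#'
#' Families:
#' \describe{
#'   \item{`ideal_gas`}{N non-interacting particles; expectation: NPT number
#'     density P/(k_B T).}
#'   \item{`lj_fluid`}{single-site LJ fluid at reduced temperature `Tstar`
#'     and density `rhostar`; expectation: dilute-limit mu_ex = 2 B2 rho kT.}
#'   \item{`charge_lattice`}{rock-salt arrangement of +/-1 e point charges
#'     with nearest-neighbour spacing `d`; expectation: Madelung energy
#'     -1.747565 ke/d per ion pair.}
#'   \item{`two_state`}{two-bin toy with probability ratio `r`; expectation:
#'     converged Wang-Landau weight difference ln r (k_B T ln r in energy
#'     units).}
#'   \item{`mu_tables`}{synthetic (T, mu_ECS, mu_PES) tables whose
#'     difference follows eps(T) = A0 + A1 T plus Gaussian noise;
#'     expectation: the generating constants.}
#' }
#'
#' @param family fixture family name
#' @param params named list of family parameters (see details above;
#'   sensible defaults otherwise)
#' @param seed integer; generation is deterministic given the seed
#' @return list with `family`, the generated objects, and `expected`
#' @export
make_fixture <- function(family, params = list(), seed = 1) {
  p <- function(name, default) {
    if (!is.null(params[[name]])) params[[name]] else default
  }
  switch(family,
    ideal_gas = {
      N <- p("N", 30L); T <- p("T", 300); P <- p("P", 1)
      sp <- lj_species("IG", epsilon = 0, sigma = 0, mass = 40)
      ff <- ff_bundle(list(sp), rc = 0.9, tail = FALSE)
      rho <- P * 0.0602214076 / kBT(T)        # nm^-3
      L <- (N / rho)^(1 / 3)
      st <- build_system(ff, c(IG = N), L = L, seed = seed)
      list(family = family, ff = ff, state = st, T = T, P = P,
           expected = list(density = rho))
    },
    lj_fluid = {
      Tstar <- p("Tstar", 1.5); rhostar <- p("rhostar", 0.3)
      N <- p("N", 40L); sigma <- p("sigma", 0.3); T <- p("T", 300)
      eps <- kBT(T) / Tstar
      sp <- lj_species("LJ", epsilon = eps, sigma = sigma, mass = 40)
      rc <- p("rc", 2.5 * sigma)
      ff <- ff_bundle(list(sp), rc = rc, tail = TRUE)
      L <- (N * sigma^3 / rhostar)^(1 / 3)
      st <- build_system(ff, c(LJ = N), L = L, seed = seed)
      list(family = family, ff = ff, state = st, T = T,
           epsilon = eps, sigma = sigma, rho = rhostar / sigma^3,
           expected = list(
             mu_ex_dilute = 2 * lj_b2(T, eps, sigma) *
               rhostar / sigma^3 * kBT(T)))
    },
    charge_lattice = {
      ncell <- p("ncell", 2L)        # unit cells per edge (2 sites/edge cell)
      d <- p("d", 0.4)               # nearest-neighbour spacing, nm
      n_edge <- 2L * ncell
      L <- n_edge * d
      sp_p <- lj_species("Qp", epsilon = 0, sigma = 0, charge = 1, mass = 1)
      sp_m <- lj_species("Qm", epsilon = 0, sigma = 0, charge = -1, mass = 1)
      ff <- ff_bundle(list(sp_p, sp_m), rc = min(0.45 * L, 0.9),
                      tail = FALSE, ewald_accuracy = 1e-7)
      grid <- expand.grid(i = 0:(n_edge - 1), j = 0:(n_edge - 1),
                          k = 0:(n_edge - 1))
      sign_site <- (-1)^(grid$i + grid$j + grid$k)
      npos <- sum(sign_site > 0)
      st <- build_system(ff, c(Qp = npos, Qm = nrow(grid) - npos),
                        L = L, seed = seed)
      pos <- as.matrix(grid[order(sign_site, decreasing = TRUE), ]) * d + d / 2
      st$com <- unname(pos)
      st$quat <- matrix(rep(c(1, 0, 0, 0), nrow(pos)), ncol = 4, byrow = TRUE)
      madelung <- 1.747564594633
      list(family = family, ff = ff, state = st, d = d,
           n_pairs = nrow(grid) / 2,
           expected = list(
             energy_per_pair = -madelung * 138.935458 / d,
             madelung = madelung))
    },
    two_state = {
      r <- p("r", 3); T <- p("T", 300)
      list(family = family, probs = c(1, r) / (1 + r), T = T,
           expected = list(delta_eta = log(r),
                           delta_f_kJ = kBT(T) * log(r)))
    },
    mu_tables = {
      A0 <- p("A0", 5.00); A1 <- p("A1", -4.36e-3)
      Ts <- p("T", c(300, 350, 400, 450, 500))
      noise <- p("noise", 0)
      mu_pes <- p("mu_pes_base", -30) + 0.02 * (Ts - Ts[1])
      rng <- .lcg(seed)
      gauss <- function(n) {
        vapply(seq_len(n), function(i) {
          u1 <- max(rng(), 1e-12); u2 <- rng()
          sqrt(-2 * log(u1)) * cos(2 * pi * u2)
        }, numeric(1))
      }
      eps_true <- A0 + A1 * Ts
      eps_noisy <- eps_true + noise * gauss(length(Ts))
      tab <- data.frame(T = Ts, mu_ecs = mu_pes + eps_noisy,
                        mu_pes = mu_pes, sigma = rep(max(noise, 1e-6),
                                                     length(Ts)))
      list(family = family, table = tab,
           expected = list(A0 = A0, A1 = A1))
    },
    stop("unknown fixture family: ", family, call. = FALSE)
  )
}

#' Wang-Landau sampling of a small discrete system
#'
#' Direct Metropolis sampling of `length(probs)` states with stationary
#' probabilities proportional to `probs`, flattened by a Wang-Landau bias
#' built with [wl_visit()] and [update_bias()]. On convergence the bias
#' weights satisfy eta_i = -ln p_i + const, so the weight differences
#' recover the free-energy differences of the toy system.
#'
#' @param probs unnormalized state probabilities
#' @param seed integer seed
#' @param f0 initial modification factor
#' @param schedule flatness schedule, see [update_bias()]
#' @param check_every sweeps between flatness checks
#' @param max_updates hard cap on per-visit updates
#' @return converged `lambda_histogram` (bins = states)
#' @export
wl_sample_discrete <- function(probs, seed = 1, f0 = 1.0,
                               schedule = list(flat = 0.8, fmin = 1e-4),
                               check_every = 1000, max_updates = 5e6) {
  ns <- length(probs)
  hist <- lambda_histogram(nbins = ns, f = f0)
  rng <- .lcg(seed)
  state <- 1L
  nup <- 0
  while (!hist$converged && nup < max_updates) {
    for (i in seq_len(check_every)) {
      prop <- floor(rng() * ns) + 1L
      if (prop > ns) prop <- ns
      arg <- log(probs[prop]) - log(probs[state]) +
        hist$eta[prop] - hist$eta[state]
      if (arg >= 0 || rng() < exp(arg)) state <- prop
      hist <- wl_visit(hist, state)
      nup <- nup + 1
    }
    hist <- update_bias(hist, schedule)
  }
  hist
}
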