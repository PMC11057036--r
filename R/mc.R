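# NPT CFCMC driver, lambda-bias bookkeeping and mu_ex estimators.

#' NPT ensemble and move-mix specification
#'
#' @param T temperature, K
#' @param P pressure, bar
#' @param move_weights numeric length-5, relative attempt weights for
#'   translate, rotate, volume, lambda and group-reinsertion moves
#'   (normalized internally; nonnegative)
#' @param dmax,rotmax,dlnV,dlam initial maximum displacements (nm, rad,
#'   ln-volume, lambda); adapted during equilibration toward 30-50%
#'   acceptance and frozen for production
#' @param nbins number of lambda bins
#' @return list of class `ensemble_spec`
#' @export
ensemble_spec <- function(T, P, move_weights = c(0.35, 0.35, 0.02, 0.14, 0.14),
                          dmax = 0.02, rotmax = 0.3, dlnV = 0.02,
                          dlam = 0.1, nbins = 41) {
  stopifnot(T > 0, P > 0, length(move_weights) == 5L,
            all(move_weights >= 0), sum(move_weights) > 0)
  structure(list(T = T, P = P,
                 move_weights = move_weights / sum(move_weights),
                 dmax = dmax, rotmax = rotmax, dlnV = dlnV, dlam = dlam,
                 nbins = nbins),
            class = "ensemble_spec")
}

.run_defaults <- function(ens, seed,
                          nsteps_equil, nsteps_prod, nblocks,
                          wl_f0 = 1.0, wl_flat = 0.8, wl_fmin = 1e-4,
                          wl_check = NULL, adapt = TRUE,
                          widom_every = 0, widom_n = 0, widom_species = 0,
                          widom_surface = "PES", sample_every = 10) {
  if (is.null(wl_check)) wl_check <- max(2000L, ens$nbins * 500L)
  list(T = ens$T, P = ens$P,
       nsteps_equil = nsteps_equil, nsteps_prod = nsteps_prod,
       nblocks = nblocks, move_weights = ens$move_weights,
       dmax = ens$dmax, rotmax = ens$rotmax, dlnV = ens$dlnV,
       dlam = ens$dlam, nbins = ens$nbins,
       wl_f0 = wl_f0, wl_flat = wl_flat, wl_fmin = wl_fmin,
       wl_check = wl_check, adapt = adapt,
       widom_every = if (widom_every > 0) widom_every else 1e18,
       widom_n = widom_n, widom_species = widom_species,
       widom_surface = widom_surface,
       sample_every = sample_every, seed = seed)
}

#' Run an NPT (CFC)MC simulation
#'
#' Performs a Wang-Landau biased equilibration stage (move maxima adapted,
#' lambda bias built up with decreasing modification factor until the visit
#' histogram is flat) followed by a production stage with frozen bias, block
#' averaging and optional Widom test insertions.
#'
#' @param ff an [ff_bundle()]
#' @param state a [build_system()] state
#' @param ensemble an [ensemble_spec()]
#' @param nsteps_equil,nsteps_prod move counts for the two stages
#' @param nblocks number of production blocks for error estimation
#' @param seed mandatory integer seed; the run is reproducible given the
#'   seed and configuration
#' @param widom_species species name to ghost-insert (NULL for none)
#' @param widom_surface charge surface for ghost insertions
#' @param widom_every,widom_n insertion cadence (steps) and insertions per
#'   sampling event
#' @param ... advanced Wang-Landau/sampling knobs passed through
#'   (`wl_f0`, `wl_flat`, `wl_fmin`, `wl_check`, `adapt`, `sample_every`)
#' @return object of class `npt_run`: block averages with standard errors
#'   (`density` molecules/nm^3, `rho_mass` kg/m^3, `u` kJ/mol per molecule),
#'   the lambda histogram (`lambda_histogram`), acceptance report, Widom
#'   accumulators, insertion tail corrections, the final state, and a
#'   settings echo including every derived constant
#' @export
run_npt <- function(ff, state, ensemble, nsteps_equil, nsteps_prod,
                    nblocks = 5, seed, widom_species = NULL,
                    widom_surface = "PES", widom_every = 50, widom_n = 5,
                    ...) {
  stopifnot(inherits(ff, "ff_bundle"), inherits(state, "system_state"),
            inherits(ensemble, "ensemble_spec"))
  if (missing(seed) || is.null(seed))
    stop("seed is mandatory for every run", call. = FALSE)
  wsp <- 0L
  if (!is.null(widom_species)) {
    wsp <- match(widom_species, ff$species_names)
    if (is.na(wsp)) stop("unknown widom species", call. = FALSE)
  }
  extra <- list(...)
  sample_pair <- isTRUE(extra$sample_pair)
  extra$sample_pair <- NULL
  run <- do.call(.run_defaults, c(
    list(ensemble, seed = seed, nsteps_equil = nsteps_equil,
         nsteps_prod = nsteps_prod, nblocks = nblocks,
         widom_every = if (wsp > 0) widom_every else 0,
         widom_n = widom_n, widom_species = wsp,
         widom_surface = widom_surface), extra))
  if (sample_pair) run$sample_pair <- TRUE
  out <- cpp_run_npt(.ff_to_cpp(ff), .state_to_cpp(state), run)
  fin <- .state_from_cpp(out$final_state)
  hist <- structure(list(
    edges = seq(0, 1, length.out = ensemble$nbins + 1L),
    counts = colSums(out$hist_blocks),
    block_counts = out$hist_blocks,
    eta = out$eta, f = out$wl_f_final,
    converged = out$wl_converged,
    fep = list(f0_sum = out$fep0_sum, f0_n = out$fep0_n,
               f1_sum = out$fep1_sum, f1_n = out$fep1_n)),
    class = "lambda_histogram")
  tail_frac <- if (length(fin$frac) > 0L) {
    cpp_insertion_tail(.ff_to_cpp(ff), .state_to_cpp(fin),
                       as.integer(fin$spid[fin$frac]))
  } else 0
  tail_widom <- if (wsp > 0L) {
    cpp_insertion_tail(.ff_to_cpp(ff), .state_to_cpp(fin), as.integer(wsp))
  } else 0
  se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  structure(list(
    T = ensemble$T, P = ensemble$P, seed = seed,
    density = list(mean = mean(out$rho_blocks), se = se(out$rho_blocks),
                   blocks = out$rho_blocks),
    rho_mass = list(mean = mean(out$rho_mass_blocks),
                    se = se(out$rho_mass_blocks),
                    blocks = out$rho_mass_blocks),
    u = list(mean = mean(out$u_blocks), se = se(out$u_blocks),
             blocks = out$u_blocks),
    volume = list(mean = mean(out$v_blocks), blocks = out$v_blocks),
    lambda_histogram = hist,
    acceptance = out$acceptance, attempts = out$attempts,
    widom = list(sum = out$widom_sum, v = out$widom_v, n = out$widom_n,
                 surface = widom_surface, species = widom_species),
    pair_dist = out$pair_dist,
    tail_mu_frac = tail_frac, tail_mu_widom = tail_widom,
    energy_drift = out$energy_drift,
    wl_converged = out$wl_converged,
    final_state = fin,
    settings = c(out$settings, list(seed = seed,
                                    nsteps_equil = nsteps_equil,
                                    nsteps_prod = nsteps_prod,
                                    nblocks = nblocks))),
    class = "npt_run")
}

#' @export
print.npt_run <- function(x, ...) {
  cat(sprintf("NPT run @ %g K, %g bar (seed %s)\n", x$T, x$P,
              format(x$seed)))
  cat(sprintf("  <rho> = %.5g +/- %.2g nm^-3 (%.4g kg/m^3)\n",
              x$density$mean, x$density$se, x$rho_mass$mean))
  cat(sprintf("  <U>/N = %.5g +/- %.2g kJ/mol, drift %.2g kJ/mol\n",
              x$u$mean, x$u$se, x$energy_drift))
  invisible(x)
}

#' Single Monte Carlo step
#'
#' Attempts one move drawn from the ensemble's move mix (Metropolis
#' acceptance, no bias updating, no adaptation) and returns the new state.
#' Mainly a building block for inspection; production sampling goes through
#' [run_npt()].
#'
#' @param state a [build_system()] state
#' @param ensemble an [ensemble_spec()]
#' @param ff an [ff_bundle()]
#' @param seed integer seed for this step
#' @return the updated `system_state`
#' @export
mc_step <- function(state, ensemble, ff, seed) {
  run <- .run_defaults(ensemble, seed = seed, nsteps_equil = 0,
                       nsteps_prod = 1, nblocks = 1, adapt = FALSE,
                       wl_f0 = 0, sample_every = 1e18)
  out <- cpp_run_npt(.ff_to_cpp(ff), .state_to_cpp(state), run)
  .state_from_cpp(out$final_state)
}

#' Metropolis acceptance probability
#'
#' min(1, exp(-dU/kBT + dbias)); the rule used by every move in the engine.
#' A null move (dU = 0, no bias change) is always accepted.
#'
#' @param delta_u energy change, kJ/mol
#' @param T temperature, K
#' @param delta_bias bias-weight change (natural-log units)
#' @return acceptance probability in `[0, 1]`
#' @export
metropolis_probability <- function(delta_u, T, delta_bias = 0) {
  if (is.infinite(delta_u) && delta_u > 0) return(0)
  min(1, exp(-delta_u / kBT(T) + delta_bias))
}

#' Create an empty lambda histogram with bias weights
#'
#' @param nbins number of bins covering `[0, 1]` without gaps
#' @param f initial Wang-Landau modification factor (natural-log units)
#' @return object of class `lambda_histogram`
#' @export
lambda_histogram <- function(nbins = 41, f = 1.0) {
  structure(list(edges = seq(0, 1, length.out = nbins + 1L),
                 counts = numeric(nbins),
                 block_counts = NULL,
                 eta = numeric(nbins), f = f, converged = FALSE),
            class = "lambda_histogram")
}

#' Record a visit in a Wang-Landau histogram
#'
#' Applies the per-visit update: the visited bin's bias weight is lowered by
#' the current modification factor and its count incremented, so that
#' frequently visited bins become less likely and sampling flattens.
#'
#' @param hist a [lambda_histogram()]
#' @param bin visited bin index (1-based)
#' @return the updated histogram
#' @export
wl_visit <- function(hist, bin) {
  hist$eta[bin] <- hist$eta[bin] - hist$f
  hist$counts[bin] <- hist$counts[bin] + 1
  hist
}

#' Wang-Landau schedule update (flatness check)
#'
#' If the visit histogram is flat (minimum count at least `flat` times the
#' mean), the modification factor is halved and the counts reset; once the
#' factor drops below `fmin` the bias is frozen (`converged = TRUE`) for
#' production. Bias weights are defined up to an additive constant (gauge);
#' the update never changes observable probabilities for a converged bias.
#'
#' @param hist a [lambda_histogram()]
#' @param schedule list with `flat` (default 0.8) and `fmin` (default 1e-4)
#' @return the updated histogram
#' @export
update_bias <- function(hist, schedule = list(flat = 0.8, fmin = 1e-4)) {
  stopifnot(inherits(hist, "lambda_histogram"))
  flat <- if (is.null(schedule$flat)) 0.8 else schedule$flat
  fmin <- if (is.null(schedule$fmin)) 1e-4 else schedule$fmin
  m <- mean(hist$counts)
  if (m > 0 && min(hist$counts) >= flat * m) {
    hist$f <- hist$f / 2
    hist$counts[] <- 0
    if (hist$f < fmin) hist$converged <- TRUE
  }
  hist
}

# unbiased ln p(lambda) at bin centers from counts and bias weights
.lnp_unbiased <- function(counts, eta) {
  lnp <- ifelse(counts > 0, log(counts) - eta, NA_real_)
  lnp
}

# ln p extrapolated to a lambda edge (0 or 1) from the two nearest bins
.lnp_edge <- function(lnp, centers, edge) {
  k <- if (edge == 0) c(1L, 2L) else c(length(lnp), length(lnp) - 1L)
  if (is.na(lnp[k[1]])) return(NA_real_)
  if (is.na(lnp[k[2]])) return(lnp[k[1]])
  slope <- (lnp[k[1]] - lnp[k[2]]) / (centers[k[1]] - centers[k[2]])
  lnp[k[1]] + slope * (edge - centers[k[1]])
}

#' Excess chemical potential from a lambda histogram
#'
#' mu_ex = -k_B T ln [ p(lambda -> 1) / p(lambda -> 0) ] with the bias
#' weights removed from the visit counts. The endpoint probabilities are
#' estimated, in order of preference:
#' \describe{
#'   \item{`"fep"`}{exact free-energy-perturbation correction of the two
#'     terminal bins, using the in-run averages of
#'     exp(-(U(edge) - U(lambda))/kBT) over visits to those bins; no
#'     discretization bias (requires the accumulators collected by
#'     [run_npt()]).}
#'   \item{`"extrapolate"`}{linear extrapolation of ln p from the two
#'     terminal bin centers to the lambda edges.}
#'   \item{`"bin"`}{raw terminal-bin probabilities.}
#' }
#' `"auto"` (default) uses `"fep"` when the accumulators are present and
#' populated, `"extrapolate"` otherwise. The uncertainty is the standard
#' error over independent production blocks. `tail_mu` adds the analytic
#' LJ tail contribution of the inserted group (see
#' [run_npt()]`$tail_mu_frac`).
#'
#' @param hist a `lambda_histogram` with production counts (e.g. from
#'   [run_npt()])
#' @param T temperature, K
#' @param tail_mu analytic insertion tail correction, kJ/mol
#' @param endpoint `"auto"`, `"fep"`, `"extrapolate"` or `"bin"`
#' @param surface,P,molality,species metadata for the returned estimate
#' @return a [mu_ex_estimate()]
#' @export
estimate_mu_ex <- function(hist, T, tail_mu = 0, endpoint = "auto",
                           surface = "PES", P = NA_real_, molality = 0,
                           species = "H2O") {
  stopifnot(inherits(hist, "lambda_histogram"))
  endpoint <- match.arg(endpoint, c("auto", "fep", "extrapolate", "bin"))
  nb <- length(hist$counts)
  centers <- (hist$edges[-1] + hist$edges[-(nb + 1L)]) / 2
  if (hist$counts[1] == 0 || hist$counts[nb] == 0)
    stop("insufficient sampling: empty terminal lambda bins", call. = FALSE)
  fep_ok <- !is.null(hist$fep) && sum(hist$fep$f0_n) > 0 &&
    sum(hist$fep$f1_n) > 0 && sum(hist$fep$f0_sum) > 0 &&
    sum(hist$fep$f1_sum) > 0
  if (endpoint == "auto") endpoint <- if (fep_ok) "fep" else "extrapolate"
  if (endpoint == "fep" && !fep_ok)
    stop("no endpoint perturbation samples in this histogram", call. = FALSE)
  one <- function(counts, fep) {
    lnp <- .lnp_unbiased(counts, hist$eta)
    if (endpoint == "bin") {
      if (is.na(lnp[1]) || is.na(lnp[nb])) return(NA_real_)
      -kBT(T) * (lnp[nb] - lnp[1])
    } else if (endpoint == "fep") {
      if (is.na(lnp[1]) || is.na(lnp[nb]) || any(fep$n <= 0) ||
          any(fep$s <= 0)) return(NA_real_)
      l1 <- lnp[nb] + log(fep$s[2] / fep$n[2])
      l0 <- lnp[1] + log(fep$s[1] / fep$n[1])
      -kBT(T) * (l1 - l0)
    } else {
      l1 <- .lnp_edge(lnp, centers, 1)
      l0 <- .lnp_edge(lnp, centers, 0)
      if (is.na(l1) || is.na(l0)) return(NA_real_)
      -kBT(T) * (l1 - l0)
    }
  }
  fep_all <- if (fep_ok) {
    list(s = c(sum(hist$fep$f0_sum), sum(hist$fep$f1_sum)),
         n = c(sum(hist$fep$f0_n), sum(hist$fep$f1_n)))
  } else list(s = c(1, 1), n = c(1, 1))
  value <- one(hist$counts, fep_all) + tail_mu
  se <- NA_real_
  if (!is.null(hist$block_counts) && nrow(hist$block_counts) > 1L) {
    bv <- vapply(seq_len(nrow(hist$block_counts)), function(b) {
      fb <- if (fep_ok) {
        list(s = c(hist$fep$f0_sum[b], hist$fep$f1_sum[b]),
             n = c(hist$fep$f0_n[b], hist$fep$f1_n[b]))
      } else fep_all
      one(hist$block_counts[b, ], fb)
    }, numeric(1))
    bv <- bv[!is.na(bv)]
    if (length(bv) > 1L) se <- stats::sd(bv) / sqrt(length(bv))
  }
  mu_ex_estimate(value, std_error = if (is.na(se)) 0 else se,
                 surface = surface, T = T, P = P, molality = molality,
                 species = species)
}

#' Excess chemical potential by Widom test insertion
#'
#' mu_ex = -k_B T ln of the volume-weighted average Boltzmann factor of
#' ghost insertions, `mean(V exp(-dU/kBT)) / mean(V)`, accumulated in
#' the NPT ensemble, from the insertion accumulators of a production run.
#' Serves as an estimator independent of the lambda path for cross-checking
#' CFCMC results.
#'
#' @param run an [run_npt()] result with Widom sampling enabled
#' @param surface,P,molality metadata for the returned estimate (defaults
#'   from the run)
#' @return a [mu_ex_estimate()]
#' @export
widom_mu_ex <- function(run, surface = NULL, P = NULL, molality = 0) {
  stopifnot(inherits(run, "npt_run"))
  w <- run$widom
  if (sum(w$n) == 0)
    stop("run has no Widom samples; enable widom_species in run_npt",
         call. = FALSE)
  kT <- kBT(run$T)
  value <- -kT * log(sum(w$sum) / sum(w$v)) + run$tail_mu_widom
  keep <- w$n > 0 & w$sum > 0
  se <- NA_real_
  if (sum(keep) > 1L) {
    bv <- -kT * log(w$sum[keep] / w$v[keep])
    se <- stats::sd(bv) / sqrt(length(bv))
  }
  mu_ex_estimate(value, std_error = if (is.na(se)) 0 else se,
                 surface = if (is.null(surface)) w$surface else surface,
                 T = run$T, P = if (is.null(P)) run$P else P,
                 molality = molality,
                 species = if (is.null(w$species)) "" else w$species)
}
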