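#' Excess chemical potential estimate
#'
#' Container tagging a simulated excess chemical potential with its
#' statistical uncertainty and thermodynamic state point.
#'
#' @param value excess chemical potential, kJ/mol
#' @param std_error standard error, kJ/mol (>= 0)
#' @param surface `"PES"` or `"ECS"`
#' @param T temperature, K
#' @param P pressure, bar
#' @param molality salt molality, mol/kg water
#' @param species species label
#' @return object of class `mu_ex_estimate`
#' @export
mu_ex_estimate <- function(value, std_error = 0, surface = "PES",
                           T = NA_real_, P = NA_real_, molality = 0,
                           species = "H2O") {
  surface <- match.arg(surface, c("PES", "ECS"))
  if (!is.numeric(std_error) || std_error < 0)
    stop("std_error must be >= 0", call. = FALSE)
  structure(list(value = value, std_error = std_error, surface = surface,
                 T = T, P = P, molality = molality, species = species),
            class = "mu_ex_estimate")
}

#' @export
print.mu_ex_estimate <- function(x, ...) {
  cat(sprintf("mu_ex[%s, %s] = %.4f +/- %.4f kJ/mol (T = %s K, m = %s)\n",
              x$species, x$surface, x$value, x$std_error,
              format(x$T), format(x$molality)))
  invisible(x)
}

#' Free-energy correction epsilon from the two charge surfaces
#'
#' The correction for species i is the difference between the excess
#' chemical potentials of the pure solvent computed on the effective charge
#' surface and on the potential-energy surface at the same state point:
#' eps_i(T) = mu_i,ECS(m=0) - mu_i,PES(m=0). It is applied as an additive,
#' volume-independent shift to the isolated-molecule partition function and
#' therefore never alters densities, structure or transport properties.
#'
#' @param mu_ecs,mu_pes [mu_ex_estimate()] objects at the same species, T, P
#'   and zero molality
#' @return list of class `epsilon_correction` with `epsilon` (kJ/mol),
#'   `std_error` (quadrature-propagated), `T`, `species` and the two inputs
#'   as `provenance`
#' @export
#' @examples
#' e <- epsilon_correction(
#'   mu_ex_estimate(-26.37, 0.1, "ECS", T = 300),
#'   mu_ex_estimate(-30.00, 0.1, "PES", T = 300))
#' e$epsilon  # 3.63 kJ/mol
epsilon_correction <- function(mu_ecs, mu_pes) {
  stopifnot(inherits(mu_ecs, "mu_ex_estimate"),
            inherits(mu_pes, "mu_ex_estimate"))
  if (mu_ecs$surface != "ECS" || mu_pes$surface != "PES")
    stop("inputs must be tagged ECS and PES respectively", call. = FALSE)
  same <- function(a, b) (is.na(a) && is.na(b)) || isTRUE(all.equal(a, b))
  if (!same(mu_ecs$T, mu_pes$T) || !same(mu_ecs$P, mu_pes$P) ||
      mu_ecs$species != mu_pes$species)
    stop("inconsistent inputs: species, T and P must match", call. = FALSE)
  if (mu_ecs$molality != 0 || mu_pes$molality != 0)
    stop("inconsistent inputs: epsilon is defined at zero molality",
         call. = FALSE)
  structure(list(
    species = mu_ecs$species,
    epsilon = mu_ecs$value - mu_pes$value,
    std_error = sqrt(mu_ecs$std_error^2 + mu_pes$std_error^2),
    T = mu_ecs$T,
    provenance = list(mu_ecs = mu_ecs, mu_pes = mu_pes)),
    class = "epsilon_correction")
}

#' Linear temperature fit of the free-energy correction
#'
#' Fits eps(T) = A0 + A1 * T by least squares. The default is ordinary
#' (unweighted) least squares; `weighted = TRUE` weights each point by
#' 1/sigma^2 using the reported uncertainties.
#'
#' @param points data.frame with columns `T` (K), `epsilon` (kJ/mol) and
#'   optionally `sigma` (kJ/mol, reported uncertainty)
#' @param weighted logical, weight by 1/sigma^2
#' @return object of class `epsilon_fit` with `A0` (kJ/mol), `A1`
#'   (kJ/mol/K), `T_range`, per-point `residuals`, and the underlying `lm`
#'   fit
#' @export
fit_epsilon_linear <- function(points, weighted = FALSE) {
  stopifnot(is.data.frame(points), all(c("T", "epsilon") %in% names(points)))
  pts <- points[stats::complete.cases(points[, c("T", "epsilon")]), ]
  if (nrow(pts) < 2L || length(unique(pts$T)) < 2L)
    stop("degenerate fit: need >= 2 points at distinct temperatures",
         call. = FALSE)
  w <- NULL
  if (weighted) {
    if (!"sigma" %in% names(pts) || any(!is.finite(pts$sigma)) ||
        any(pts$sigma <= 0))
      stop("weighted fit requires positive finite sigma for every point",
           call. = FALSE)
    w <- 1 / pts$sigma^2
  }
  fit <- stats::lm(epsilon ~ T, data = pts, weights = w)
  co <- stats::coef(fit)
  structure(list(
    A0 = unname(co[1L]), A1 = unname(co[2L]),
    T_range = range(pts$T),
    residuals = data.frame(T = pts$T, residual = stats::residuals(fit)),
    fit = fit),
    class = "epsilon_fit")
}

#' Evaluate an epsilon fit at given temperatures
#' @param fit an `epsilon_fit` (or a list with `A0`, `A1`)
#' @param T temperatures, K
#' @return epsilon values, kJ/mol
#' @export
epsilon_at <- function(fit, T) fit$A0 + fit$A1 * T

#' @export
print.epsilon_fit <- function(x, ...) {
  cat(sprintf("eps(T) = %.4f %+.4e * T  kJ/mol  (fit over %g-%g K)\n",
              x$A0, x$A1, x$T_range[1], x$T_range[2]))
  invisible(x)
}

#' Total chemical potential with the ECS free-energy correction
#'
#' mu_i = mu_id + mu_ex,PES + eps_i. Pure addition: the sampling surface is
#' untouched and no resampling is involved.
#'
#' @param mu_id ideal-gas contribution, kJ/mol
#' @param mu_ex_pes excess chemical potential on the PES, kJ/mol
#' @param eps free-energy correction, kJ/mol (scalar or an
#'   `epsilon_correction`)
#' @param species label
#' @return list of class `chemical_potential_record` with `mu_total` and the
#'   three components
#' @export
corrected_mu <- function(mu_id, mu_ex_pes, eps, species = "H2O") {
  if (inherits(eps, "epsilon_correction")) eps <- eps$epsilon
  structure(list(species = species, mu_id = mu_id, mu_ex_pes = mu_ex_pes,
                 epsilon = eps, mu_total = mu_id + mu_ex_pes + eps),
            class = "chemical_potential_record")
}

#' Water activity from PES excess chemical potentials and number densities
#'
#' k_B T ln a_w = (mu_w,PES,m - mu_w,PES,0) + k_B T ln(rho_m / rho_0), where
#' rho are ensemble-averaged water number densities at molality m and 0.
#' The free-energy correction eps_w is molality-independent at fixed T and
#' cancels exactly, so activities depend only on the sampling surface.
#'
#' @param mu_ex_pes_m,mu_ex_pes_0 excess chemical potentials of water on the
#'   PES at molality m and 0, kJ/mol
#' @param rho_m,rho_0 water number densities at molality m and 0 (any common
#'   unit; only the ratio enters)
#' @param T temperature, K
#' @param molality salt molality, mol/kg water
#' @param nu_ions ions per formula unit on full dissociation (2 for NaCl,
#'   3 for MgCl2); used for the water mole fraction
#' @return list of class `activity_record` with `a_w`, `gamma_w`, `x_w`,
#'   `molality`
#' @export
#' @examples
#' water_activity(-30, -30, 0.9, 1.0, 300, molality = 1)$a_w  # 0.9
water_activity <- function(mu_ex_pes_m, mu_ex_pes_0, rho_m, rho_0, T,
                           molality = 0, nu_ions = 2) {
  if (!is.numeric(rho_m) || !is.numeric(rho_0) || rho_m <= 0 || rho_0 <= 0)
    stop("number densities must be positive", call. = FALSE)
  kT <- kBT(T)
  ln_aw <- (mu_ex_pes_m - mu_ex_pes_0) / kT + log(rho_m / rho_0)
  a_w <- exp(ln_aw)
  n_w <- 1000 / .MW_WATER                 # mol water per kg water
  x_w <- n_w / (n_w + nu_ions * molality)
  structure(list(molality = molality, a_w = a_w, gamma_w = a_w / x_w,
                 x_w = x_w, rho_w_m = rho_m, rho_w_0 = rho_0, T = T),
            class = "activity_record")
}

#' Hydration free energy normalized by the integer cation charge
#'
#' Infinite-dilution hydration free energies of salts span very different
#' magnitudes for mono- and divalent cations; dividing by the integer cation
#' charge z_c (1 for Na+, K+, Li+; 2 for Mg2+, Ca2+) puts them on a common
#' scale.
#'
#' @param mu_ex_salt infinite-dilution hydration free energy of the ion
#'   pair, kJ/mol
#' @param z_c integer cation charge, 1 or 2
#' @param salt label
#' @return list of class `hydration_record` with `mu_ex`, `z_c` and
#'   `mu_ex_per_zc`
#' @export
normalized_hydration <- function(mu_ex_salt, z_c, salt = "") {
  if (!z_c %in% c(1L, 2L))
    stop("unsupported cation charge: z_c must be 1 or 2", call. = FALSE)
  structure(list(salt = salt, mu_ex = mu_ex_salt, z_c = as.integer(z_c),
                 mu_ex_per_zc = mu_ex_salt / z_c),
            class = "hydration_record")
}

#' Heat of vaporization of a rigid-molecule liquid
#'
#' For a rigid non-polarizable model with the vapor treated as an ideal gas
#' and the liquid PV term neglected, Delta H_vap = -u + R T where u is the
#' average intermolecular potential energy per molecule of the liquid.
#'
#' @param u liquid per-molecule potential energy, kJ/mol (negative for a
#'   bound liquid)
#' @param T temperature, K
#' @return Delta H_vap, kJ/mol
#' @export
#' @examples
#' heat_of_vaporization(0, 298.15)      # RT = 2.479 kJ/mol
#' heat_of_vaporization(-47.7, 298.15)  # ~50.2 kJ/mol
heat_of_vaporization <- function(u, T) {
  stopifnot(T > 0)
  -u + .kB * T
}

#' ECS-corrected heat of vaporization
#'
#' The free-energy correction eps(T) shifts the liquid chemical potential;
#' by the Gibbs-Helmholtz relation the corresponding enthalpy shift of the
#' liquid is h_corr = eps - T deps/dT, which for the linear fit
#' eps(T) = A0 + A1 T equals A0. The corrected heat of vaporization is
#' therefore Delta H_vap = -u + R T - (eps - T deps/dT).
#'
#' @param u liquid per-molecule potential energy on the PES, kJ/mol
#' @param T temperature, K
#' @param eps_fit an `epsilon_fit` (see [fit_epsilon_linear()])
#' @return Delta H_vap on the effective charge surface, kJ/mol
#' @export
heat_of_vaporization_ecs <- function(u, T, eps_fit) {
  h_corr <- epsilon_at(eps_fit, T) - T * eps_fit$A1
  heat_of_vaporization(u, T) - h_corr
}
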