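# Vapor-liquid coexistence from liquid excess chemical potentials.
#
# The saturation condition for a one-component vapor over an (incompressible)
# liquid reads
#     P_sat = (rho_L k_B T / phi_w(T, P_sat)) * exp(mu_ex / (k_B T))
# where mu_ex is the liquid-phase excess chemical potential and phi_w the
# vapor fugacity coefficient. phi_w comes from the Peng-Robinson equation of
# state, which also supplies the coexisting vapor density.

.R_J <- 8.31446261815324  # J/(mol K)

# default Peng-Robinson constants for water
.PR_WATER <- list(Tc = 647.096, Pc = 220.64, omega = 0.3443)

.pr_AB <- function(T, P_pa, Tc, Pc_pa, omega) {
  kap <- 0.37464 + 1.54226 * omega - 0.26992 * omega^2
  alpha <- (1 + kap * (1 - sqrt(T / Tc)))^2
  a <- 0.45724 * .R_J^2 * Tc^2 / Pc_pa * alpha
  b <- 0.07780 * .R_J * Tc / Pc_pa
  list(A = a * P_pa / (.R_J * T)^2, B = b * P_pa / (.R_J * T))
}

# largest real root of the PR cubic in Z (vapor branch)
.pr_vapor_Z <- function(A, B) {
  cf <- c(-(A * B - B^2 - B^3), A - 3 * B^2 - 2 * B, -(1 - B), 1)
  rt <- polyroot(cf)
  re <- Re(rt)[abs(Im(rt)) < 1e-9 * pmax(1, Mod(rt))]
  re <- re[re > B]
  if (length(re) == 0L) {
    warning("no vapor root above B; using largest real root", call. = FALSE)
    re <- max(Re(rt))
  }
  list(Z = max(re), n_real = length(re))
}

#' Peng-Robinson fugacity coefficient of a pure vapor
#'
#' Solves the Peng-Robinson cubic for the vapor compressibility root and
#' evaluates the closed-form fugacity coefficient. Defaults are the accepted
#' critical constants of water (Tc = 647.096 K, Pc = 220.64 bar,
#' omega = 0.3443).
#'
#' @param T temperature, K
#' @param P pressure, bar
#' @param Tc critical temperature, K
#' @param Pc critical pressure, bar
#' @param omega acentric factor
#' @return list with `phi` (fugacity coefficient), `Z` (vapor
#'   compressibility factor)
#' @export
#' @examples
#' pr_fugacity_coefficient(300, 0.0354)$phi  # within 1e-3 of 1
pr_fugacity_coefficient <- function(T, P, Tc = .PR_WATER$Tc,
                                    Pc = .PR_WATER$Pc,
                                    omega = .PR_WATER$omega) {
  stopifnot(T > 0, P > 0)
  ab <- .pr_AB(T, P * 1e5, Tc, Pc * 1e5, omega)
  A <- ab$A; B <- ab$B
  Z <- .pr_vapor_Z(A, B)$Z
  s2 <- sqrt(2)
  lnphi <- (Z - 1) - log(Z - B) -
    A / (2 * s2 * B) * log((Z + (1 + s2) * B) / (Z + (1 - s2) * B))
  list(phi = exp(lnphi), Z = Z)
}

#' Peng-Robinson vapor density
#'
#' Molar and mass density of the vapor phase from the same compressibility
#' root used by [pr_fugacity_coefficient()].
#'
#' @inheritParams pr_fugacity_coefficient
#' @param molar_mass molar mass, g/mol (water by default)
#' @return list with `rho_molar` (mol/m^3) and `rho_mass` (kg/m^3)
#' @export
pr_vapor_density <- function(T, P, Tc = .PR_WATER$Tc, Pc = .PR_WATER$Pc,
                             omega = .PR_WATER$omega, molar_mass = 18.015) {
  Z <- pr_fugacity_coefficient(T, P, Tc, Pc, omega)$Z
  rho_molar <- (P * 1e5) / (Z * .R_J * T)
  list(rho_molar = rho_molar, rho_mass = rho_molar * molar_mass / 1000)
}

#' Saturated vapor pressure from the liquid excess chemical potential
#'
#' Iterates P = (rho_L k_B T / phi(T, P)) exp(mu_ex / k_B T) to a fixed
#' point, starting from phi = 1 (damped fixed-point iteration; the
#' dependence of phi on P is weak below a few bar, so convergence is fast).
#' The liquid is treated as incompressible: rho_L and mu_ex are taken at a
#' single reference pressure regardless of P_sat.
#'
#' @param T temperature, K
#' @param rho_l_molar liquid number density of water, mol/L
#' @param mu_ex liquid excess chemical potential (ECS-corrected when the
#'   correction applies), kJ/mol
#' @param phi_fixed if non-NULL, bypass the equation of state and use this
#'   constant fugacity coefficient (useful for closed-form checks)
#' @param Tc,Pc,omega Peng-Robinson constants for the vapor
#' @param molar_mass molar mass of the vapor species, g/mol
#' @param tol relative fixed-point tolerance
#' @param max_iter maximum iterations
#' @param damping fixed-point damping factor in (0, 1]
#' @param molality salt molality tag carried into the result
#' @return list of class `coexistence_point` with `T`, `P_sat` (bar),
#'   `rho_L` (kg/m^3), `rho_G` (kg/m^3), `phi_w`, `molality`, `residual`
#'   (kJ/mol, self-consistency of the saturation relation) and `iterations`
#' @export
#' @examples
#' # printed worked example: experimental mu_ex at 300 K
#' solve_psat(300, 55.32, -26.37, phi_fixed = 1)$P_sat * 100  # ~3.5 kPa
solve_psat <- function(T, rho_l_molar, mu_ex, phi_fixed = NULL,
                       Tc = .PR_WATER$Tc, Pc = .PR_WATER$Pc,
                       omega = .PR_WATER$omega, molar_mass = 18.015,
                       tol = 1e-13, max_iter = 500, damping = 1,
                       molality = 0) {
  stopifnot(T > 0, rho_l_molar > 0)
  kT <- kBT(T)
  # ideal-gas pressure of the liquid number density, in bar
  P_ref <- rho_l_molar * 1000 * .R_J * T / 1e5
  boltz <- exp(mu_ex / kT)
  phi_of <- if (is.null(phi_fixed)) {
    function(P) pr_fugacity_coefficient(T, P, Tc, Pc, omega)$phi
  } else {
    function(P) phi_fixed
  }
  P <- P_ref * boltz            # phi = 1 start
  iter <- 0L
  repeat {
    iter <- iter + 1L
    phi <- phi_of(P)
    P_new <- P_ref * boltz / phi
    P_next <- (1 - damping) * P + damping * P_new
    if (abs(P_next - P) <= tol * max(P, 1e-300)) { P <- P_next; break }
    P <- P_next
    if (iter >= max_iter)
      stop(sprintf(
        "saturation-pressure iteration did not converge in %d steps (last rel. change %.3g)",
        max_iter, abs(P_new - P) / P), call. = FALSE)
  }
  phi <- phi_of(P)
  residual <- mu_ex - kT * log(phi * P / P_ref)
  rho_G <- if (is.null(phi_fixed)) {
    pr_vapor_density(T, P, Tc, Pc, omega, molar_mass)$rho_mass
  } else {
    (P * 1e5) / (.R_J * T) * molar_mass / 1000   # ideal vapor
  }
  structure(list(T = T, P_sat = P, rho_L = rho_l_molar * molar_mass,
                 rho_G = rho_G, phi_w = phi, molality = molality,
                 residual = residual, iterations = iter),
            class = "coexistence_point")
}

#' @export
print.coexistence_point <- function(x, ...) {
  cat(sprintf(
    "T = %g K, m = %g: P_sat = %.6g bar, rho_G = %.4g kg/m^3, phi_w = %.6f\n",
    x$T, x$molality, x$P_sat, x$rho_G, x$phi_w))
  invisible(x)
}

#' Coexistence point of a salt solution from the water activity
#'
#' Over an electrolyte solution (salt non-volatile, vapor pure water) the
#' liquid water chemical potential is shifted by k_B T ln a_w relative to the
#' pure solvent, which lowers the saturation pressure. The liquid density and
#' zero-molality chemical potential are evaluated at a 1 bar reference
#' (incompressible-liquid assumption).
#'
#' @param T temperature, K
#' @param rho_l_molar water number density of the solution at molality m,
#'   mol/L
#' @param mu_ex0 ECS-corrected excess chemical potential of pure water at T,
#'   kJ/mol
#' @param a_w water activity at molality m, in (0, 1]
#' @param molality salt molality, mol/kg water (metadata)
#' @param ... passed to [solve_psat()]
#' @return a `coexistence_point` (see [solve_psat()])
#' @export
coexistence_with_salt <- function(T, rho_l_molar, mu_ex0, a_w,
                                  molality = NA_real_, ...) {
  if (!is.numeric(a_w) || a_w <= 0 || a_w > 1)
    stop("water activity must be in (0, 1]", call. = FALSE)
  mu_eff <- mu_ex0 + kBT(T) * log(a_w)
  solve_psat(T, rho_l_molar, mu_eff, molality = molality, ...)
}
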