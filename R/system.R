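# System and force-field bundle construction for the MC engine.

# tiny deterministic generator for initial orientations/placements, so that
# system construction never touches R's global RNG state
.lcg <- function(seed) {
  s <- as.numeric(seed) %% 2147483647
  if (s <= 0) s <- s + 2147483646
  function() {
    s <<- (s * 48271) %% 2147483647
    s / 2147483647
  }
}

#' Bundle species into an engine-ready force field
#'
#' Assigns a global LJ type to every site, builds the pairwise epsilon/sigma
#' tables by [cross_interaction()] (Lorentz-Berthelot plus optional pair
#' overrides), and fixes the interaction settings: cutoff, LJ tail
#' correction, Ewald accuracy and soft-core parameter.
#'
#' @param species list of [molecular_species()]
#' @param rc site-site cutoff for LJ and real-space Ewald, nm
#' @param tail logical, apply the analytic LJ tail correction
#' @param ewald_accuracy relative Ewald accuracy target; the screening
#'   parameter alpha and the reciprocal-space cutoff are derived from it
#' @param sc_alpha Beutler soft-core parameter for the lambda-coupled group
#' @param overrides optional pair-override data.frame (see
#'   [cross_interaction()])
#' @param warn_lb warn on Lorentz-Berthelot fallback for cross pairs between
#'   different species when overrides were supplied
#' @return list of class `ff_bundle`
#' @export
ff_bundle <- function(species, rc = 0.9, tail = TRUE,
                      ewald_accuracy = 1e-5, sc_alpha = 0.5,
                      overrides = NULL, warn_lb = FALSE) {
  stopifnot(is.list(species),
            all(vapply(species, inherits, TRUE, "molecular_species")))
  all_sites <- list()
  sp_cpp <- list()
  tcount <- 0L
  for (si in seq_along(species)) {
    sp <- species[[si]]
    ns <- length(sp$sites)
    types <- integer(ns)
    for (j in seq_len(ns)) {
      tcount <- tcount + 1L
      types[j] <- tcount
      all_sites[[tcount]] <- sp$sites[[j]]
    }
    body <- t(vapply(sp$sites, function(s) s$position, numeric(3)))
    sp_cpp[[si]] <- list(
      body = body, type = types,
      q_pes = sp$charge_sets$PES$charges,
      q_ecs = sp$charge_sets$ECS$charges,
      mass = sp$mass)
  }
  eps <- matrix(0, tcount, tcount)
  sig <- matrix(0, tcount, tcount)
  for (a in seq_len(tcount))
    for (b in seq_len(a)) {
      pr <- cross_interaction(all_sites[[a]], all_sites[[b]], overrides,
                              warn_lb = warn_lb && a != b)
      eps[a, b] <- eps[b, a] <- pr$epsilon
      sig[a, b] <- sig[b, a] <- pr$sigma
    }
  structure(list(
    species = sp_cpp,
    species_names = vapply(species, function(s) s$name, character(1)),
    species_objects = species,
    eps = eps, sig = sig, rc = rc, tail = tail,
    ewald_accuracy = ewald_accuracy, sc_alpha = sc_alpha),
    class = "ff_bundle")
}

.ff_to_cpp <- function(ff) {
  list(species = ff$species, eps = ff$eps, sig = ff$sig, rc = ff$rc,
       tail = ff$tail, ewald_accuracy = ff$ewald_accuracy,
       sc_alpha = ff$sc_alpha)
}

#' Build an initial system state on a cubic lattice
#'
#' Molecules are placed on a simple cubic lattice inside a cubic periodic box
#' and given random orientations (deterministic given `seed`). The fractional
#' group, if any, consists of the last molecules of the listed species.
#'
#' @param ff an [ff_bundle()]
#' @param counts named integer vector: species name -> number of molecules
#'   (fractional group members included)
#' @param L box edge, nm (give either `L` or `rho_mass`)
#' @param rho_mass target mass density, kg/m^3
#' @param frac named integer vector: species name -> number of molecules of
#'   that species assigned to the fractional group (NULL for none)
#' @param lambda initial coupling parameter
#' @param frac_surface `"PES"` or `"ECS"`: charge set used by the group
#' @param seed integer seed for the placement generator
#' @return list of class `system_state`
#' @export
build_system <- function(ff, counts, L = NULL, rho_mass = NULL,
                         frac = NULL, lambda = 1, frac_surface = "PES",
                         seed = 1) {
  stopifnot(inherits(ff, "ff_bundle"))
  frac_surface <- match.arg(frac_surface, c("PES", "ECS"))
  idx <- match(names(counts), ff$species_names)
  if (anyNA(idx))
    stop("unknown species in counts: ",
         paste(names(counts)[is.na(idx)], collapse = ", "), call. = FALSE)
  spid <- rep(idx, counts)
  n <- length(spid)
  if (is.null(L)) {
    if (is.null(rho_mass))
      stop("give either L or rho_mass", call. = FALSE)
    masses <- vapply(ff$species, function(s) s$mass, numeric(1))
    mtot <- sum(masses[spid])
    V <- mtot * 1.66053906892 / rho_mass      # nm^3
    L <- V^(1 / 3)
  }
  rng <- .lcg(seed)
  ncell <- ceiling(n^(1 / 3))
  a <- L / ncell
  com <- matrix(0, n, 3)
  k <- 0L
  for (i in seq_len(ncell)) for (j in seq_len(ncell)) for (m in seq_len(ncell)) {
    if (k >= n) break
    k <- k + 1L
    com[k, ] <- (c(i, j, m) - 0.5) * a
  }
  quat <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    g <- c(rng(), rng(), rng(), rng()) * 2 - 1
    while (sum(g^2) < 1e-12) g <- c(rng(), rng(), rng(), rng()) * 2 - 1
    quat[i, ] <- g / sqrt(sum(g^2))
  }
  frac_idx <- integer(0)
  if (!is.null(frac)) {
    for (nm in names(frac)) {
      si <- match(nm, ff$species_names)
      if (is.na(si)) stop("unknown fractional species: ", nm, call. = FALSE)
      cand <- which(spid == si)
      if (length(cand) < frac[[nm]])
        stop("not enough molecules of ", nm, " for the fractional group",
             call. = FALSE)
      frac_idx <- c(frac_idx, utils::tail(cand, frac[[nm]]))
    }
  }
  structure(list(L = L, spid = spid, com = com, quat = quat,
                 frac = as.integer(frac_idx), lambda = lambda,
                 frac_surface = frac_surface),
            class = "system_state")
}

.state_to_cpp <- function(st) {
  list(L = st$L, spid = as.integer(st$spid), com = st$com, quat = st$quat,
       frac = as.integer(st$frac), lambda = st$lambda,
       frac_surface = st$frac_surface)
}

.state_from_cpp <- function(sl) {
  structure(list(L = sl$L, spid = sl$spid, com = sl$com, quat = sl$quat,
                 frac = sl$frac, lambda = sl$lambda,
                 frac_surface = sl$frac_surface),
            class = "system_state")
}

#' Total potential energy of a system state
#'
#' Lennard-Jones (truncated, with analytic tail correction) plus Ewald
#' electrostatics (real, reciprocal, self and intramolecular-exclusion
#' terms). Interactions of the fractional group are coupled at the state's
#' lambda. Overlapping sites below the hard-core distance yield `+Inf`
#' (a rejectable, not an error, condition).
#'
#' @param state a [build_system()] state
#' @param ff an [ff_bundle()]
#' @param components logical: return the energy decomposition instead of the
#'   total
#' @return total energy in kJ/mol, or a named list of components
#' @export
total_energy <- function(state, ff, components = FALSE) {
  res <- cpp_total_energy(.ff_to_cpp(ff), .state_to_cpp(state))
  if (components) res else res$total
}

#' Coupling energy of the fractional group at a given lambda
#'
#' Interaction energy between the fractional group and its surroundings
#' (including in-group intermolecular terms) at coupling parameter
#' `lambda`: soft-core LJ is switched on over the first half of the lambda
#' path and charges are scaled linearly over the second half. By
#' construction the value is 0 at lambda = 0 and equals the fully coupled
#' group contribution at lambda = 1.
#'
#' @param state a [build_system()] state with a fractional group
#' @param lambda coupling parameter in `[0, 1]`
#' @param ff an [ff_bundle()]
#' @return energy, kJ/mol
#' @export
lambda_coupled_energy <- function(state, lambda, ff) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a scalar in [0, 1]", call. = FALSE)
  if (length(state$frac) == 0L)
    stop("state has no fractional group", call. = FALSE)
  cpp_group_energy(.ff_to_cpp(ff), .state_to_cpp(state), lambda)
}
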