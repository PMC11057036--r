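#' Interaction site of a rigid molecule
#'
#' A site carries Lennard-Jones parameters, a (PES) partial charge, a mass and
#' a position in the molecule's body frame. Massless virtual sites (such as
#' the M site of four-site water models) are allowed.
#'
#' @param name site label, e.g. "O", "H1", "M"
#' @param lj_epsilon LJ well depth, kJ/mol (>= 0)
#' @param lj_sigma LJ diameter, nm (>= 0)
#' @param charge partial charge on the potential-energy surface, e
#' @param position numeric length-3, body-frame coordinates (nm)
#' @param mass site mass, g/mol (0 for virtual sites)
#' @return object of class `site_spec`
#' @export
site_spec <- function(name, lj_epsilon = 0, lj_sigma = 0, charge = 0,
                      position = c(0, 0, 0), mass = 0) {
  if (!is.numeric(lj_epsilon) || lj_epsilon < 0)
    stop("lj_epsilon must be >= 0", call. = FALSE)
  if (!is.numeric(lj_sigma) || lj_sigma < 0)
    stop("lj_sigma must be >= 0", call. = FALSE)
  if (length(position) != 3L || !is.numeric(position))
    stop("position must be a numeric 3-vector", call. = FALSE)
  structure(
    list(name = as.character(name), lj_epsilon = lj_epsilon,
         lj_sigma = lj_sigma, charge = charge,
         position = as.numeric(position), mass = mass),
    class = "site_spec"
  )
}

#' Ordered set of site charges on one charge surface
#'
#' @param label `"PES"` (sampling surface) or `"ECS"` (effective charge
#'   surface used for free-energy evaluation)
#' @param charges numeric vector of site charges (e), in site order
#' @return object of class `charge_set`
#' @export
charge_set <- function(label, charges) {
  label <- match.arg(label, c("PES", "ECS"))
  structure(list(label = label, charges = as.numeric(charges)),
            class = "charge_set")
}

#' Scale every charge of a charge set by a common factor
#'
#' This is the elementary operation behind the effective charge surface: the
#' ECS of a species is its PES charge set multiplied by a single
#' temperature-independent scalar (0.965 for four-site water models derived
#' from TIP4P/2005). Scaling preserves site order and scales the net charge
#' linearly, so a neutral molecule stays neutral.
#'
#' @param base a [charge_set()]
#' @param factor positive dimensionless scalar
#' @param label label for the result (defaults to the base label)
#' @return a new [charge_set()]
#' @export
#' @examples
#' pes <- charge_set("PES", c(0, 0.5564, 0.5564, -1.1128))  # O H H M
#' scale_charges(pes, 0.965)
scale_charges <- function(base, factor, label = base$label) {
  stopifnot(inherits(base, "charge_set"))
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0)
    stop("charge scaling factor must be a positive finite scalar",
         call. = FALSE)
  charge_set(label, base$charges * factor)
}

#' ECS charge set for a chloride-salt ion group
#'
#' The effective charge surface for ions uses +0.95/-0.95 e for monovalent
#' ion pairs; for divalent cations the cation ECS charge is multiplied by the
#' valency (+1.90 e) and is balanced by the stoichiometric number of -0.95 e
#' anions. The group is always charge-neutral.
#'
#' @param cation_valence integer 1 or 2
#' @param anion_count number of monovalent anions (defaults to the valence,
#'   as for chloride salts M Cl_v)
#' @return a [charge_set()] for the ion group, cation first
#' @export
#' @examples
#' ecs_salt_charge_set(1)  # NaCl-type: +0.95, -0.95
#' ecs_salt_charge_set(2)  # MgCl2-type: +1.90, -0.95, -0.95
ecs_salt_charge_set <- function(cation_valence, anion_count = cation_valence) {
  if (!cation_valence %in% c(1L, 2L))
    stop("unsupported species: cation valence must be 1 or 2", call. = FALSE)
  if (anion_count != cation_valence)
    stop("anion count must equal the cation valence for chloride salts",
         call. = FALSE)
  q_unit <- 0.95
  charge_set("ECS", c(q_unit * cation_valence, rep(-q_unit, anion_count)))
}

#' Pair Lennard-Jones parameters for two sites
#'
#' Returns the override pair parameters if present in `overrides`, otherwise
#' the Lorentz-Berthelot combination (arithmetic mean of sigma, geometric
#' mean of epsilon). Bespoke cross terms of published ion force fields (such
#' as the Madrid-2019 cation-oxygen pairs) must be supplied through
#' `overrides`; the Lorentz-Berthelot fallback emits a warning once per call
#' when overrides are expected (`warn_lb = TRUE`).
#'
#' @param a,b [site_spec()] objects
#' @param overrides `NULL` or a data.frame with columns
#'   `site_a, site_b, epsilon, sigma` (site names, unordered pairs)
#' @param warn_lb warn when falling back to Lorentz-Berthelot even though an
#'   override table was supplied
#' @return list with elements `epsilon` (kJ/mol) and `sigma` (nm)
#' @export
cross_interaction <- function(a, b, overrides = NULL, warn_lb = FALSE) {
  stopifnot(inherits(a, "site_spec"), inherits(b, "site_spec"))
  if (!is.null(overrides) && nrow(overrides) > 0L) {
    hit <- (overrides$site_a == a$name & overrides$site_b == b$name) |
           (overrides$site_a == b$name & overrides$site_b == a$name)
    if (any(hit)) {
      row <- overrides[which(hit)[1L], ]
      if (row$epsilon < 0 || row$sigma < 0)
        stop("override pair parameters must be non-negative", call. = FALSE)
      return(list(epsilon = row$epsilon, sigma = row$sigma))
    }
    if (warn_lb)
      warning(sprintf(
        "no override for pair (%s, %s); using Lorentz-Berthelot",
        a$name, b$name), call. = FALSE)
  }
  list(epsilon = sqrt(a$lj_epsilon * b$lj_epsilon),
       sigma = (a$lj_sigma + b$lj_sigma) / 2)
}

#' Rigid molecular species with dual charge surfaces
#'
#' Geometry and LJ parameters are shared between the PES and ECS variants of
#' a species; only the charges differ. If `charge_sets` is not given, the PES
#' set is taken from the site charges and the ECS set from scaling by
#' `ecs_factor`.
#'
#' @param name species label
#' @param sites list of [site_spec()]
#' @param charge_sets optional named list `list(PES = , ECS = )` of
#'   [charge_set()] objects
#' @param ecs_factor scalar used to derive the ECS set when `charge_sets` is
#'   absent
#' @param net_charge formal net charge of the species on the PES (e);
#'   0 for molecules, the scaled partial charge for ions
#' @return object of class `molecular_species`
#' @export
molecular_species <- function(name, sites, charge_sets = NULL,
                              ecs_factor = 1, net_charge = NULL) {
  stopifnot(is.list(sites), all(vapply(sites, inherits, TRUE, "site_spec")))
  q_pes <- vapply(sites, function(s) s$charge, numeric(1))
  if (is.null(charge_sets)) {
    pes <- charge_set("PES", q_pes)
    charge_sets <- list(PES = pes, ECS = scale_charges(pes, ecs_factor, "ECS"))
  }
  if (is.null(net_charge)) net_charge <- sum(q_pes)
  structure(
    list(name = as.character(name), sites = sites,
         charge_sets = charge_sets, rigid = TRUE,
         net_charge = net_charge,
         mass = sum(vapply(sites, function(s) s$mass, numeric(1)))),
    class = "molecular_species"
  )
}

#' @export
print.molecular_species <- function(x, ...) {
  cat(sprintf("<molecular_species> %s: %d sites, mass %.3f g/mol\n",
              x$name, length(x$sites), x$mass))
  for (i in seq_along(x$sites)) {
    s <- x$sites[[i]]
    cat(sprintf("  %-3s eps=%.6g sig=%.6g q_PES=%+.5f q_ECS=%+.5f\n",
                s$name, s$lj_epsilon, s$lj_sigma,
                x$charge_sets$PES$charges[i], x$charge_sets$ECS$charges[i]))
  }
  invisible(x)
}

#' Charge-neutral fractional group specification
#'
#' A fractional group is the set of molecules/ions that share the CFCMC
#' coupling parameter lambda: a single molecule for water, the full
#' stoichiometric ion set for a salt (e.g. one Mg2+ and two Cl- for MgCl2).
#' The group must be charge-neutral under both charge surfaces.
#'
#' @param composition named integer vector: species name -> count
#' @param charge_set_in_use `"PES"` or `"ECS"`
#' @return object of class `fractional_group`
#' @export
fractional_group <- function(composition, charge_set_in_use = "PES") {
  charge_set_in_use <- match.arg(charge_set_in_use, c("PES", "ECS"))
  stopifnot(length(names(composition)) == length(composition))
  structure(list(composition = composition,
                 charge_set_in_use = charge_set_in_use),
            class = "fractional_group")
}

#' Validate a molecular species or a species set with a fractional group
#'
#' Checks the structural invariants: rigidity, equal length and site order of
#' the PES and ECS charge sets, net charge of each charge set consistent with
#' the species' formal charge scaled appropriately, and (when a
#' [fractional_group()] is supplied along with the species list) charge
#' neutrality of the group under both surfaces.
#'
#' @param s a [molecular_species()], or a list of them
#' @param group optional [fractional_group()] to validate against `s`
#' @param tol numeric tolerance on charge sums (e)
#' @return list with `pass` (logical) and `messages` (character); report-only,
#'   never throws
#' @export
validate_species <- function(s, group = NULL, tol = 1e-9) {
  msgs <- character(0)
  species <- if (inherits(s, "molecular_species")) list(s) else s
  for (sp in species) {
    if (!inherits(sp, "molecular_species")) {
      msgs <- c(msgs, "not a molecular_species object")
      next
    }
    if (!isTRUE(sp$rigid))
      msgs <- c(msgs, sprintf("%s: only rigid species are supported", sp$name))
    ns <- length(sp$sites)
    for (lab in c("PES", "ECS")) {
      cs <- sp$charge_sets[[lab]]
      if (is.null(cs)) {
        msgs <- c(msgs, sprintf("%s: missing %s charge set", sp$name, lab))
        next
      }
      if (length(cs$charges) != ns)
        msgs <- c(msgs, sprintf(
          "%s: %s charge set has %d charges for %d sites",
          sp$name, lab, length(cs$charges), ns))
    }
    # a neutral species must be neutral on both surfaces; an ion's surfaces
    # may carry different scaled charges but must share the sign pattern
    if (abs(sp$net_charge) < tol) {
      for (lab in c("PES", "ECS")) {
        cs <- sp$charge_sets[[lab]]
        if (!is.null(cs) && length(cs$charges) == ns &&
            abs(sum(cs$charges)) > tol)
          msgs <- c(msgs, sprintf(
            "%s: neutral species has non-zero %s net charge %.3g e",
            sp$name, lab, sum(cs$charges)))
      }
    }
  }
  if (!is.null(group)) {
    names_avail <- vapply(species, function(x) x$name, character(1))
    for (lab in c("PES", "ECS")) {
      qtot <- 0
      ok <- TRUE
      for (nm in names(group$composition)) {
        i <- match(nm, names_avail)
        if (is.na(i)) {
          msgs <- c(msgs, sprintf("fractional group species '%s' not found", nm))
          ok <- FALSE
          next
        }
        qtot <- qtot +
          group$composition[[nm]] * sum(species[[i]]$charge_sets[[lab]]$charges)
      }
      if (ok && abs(qtot) > tol)
        msgs <- c(msgs, sprintf(
          "fractional group is not neutral on the %s (net %.3g e)", lab, qtot))
    }
  }
  list(pass = length(msgs) == 0L, messages = msgs)
}

#' Four-site rigid water (TIP4P/2005 geometry) with PES and ECS charges
#'
#' Builds the bundled water species: O-H bond 0.09572 nm, H-O-H angle
#' 104.52 degrees, massless M site 0.01546 nm from O on the bisector, LJ on
#' the O site (epsilon = 0.7749 kJ/mol, sigma = 0.31589 nm), PES charges
#' q_H = +0.5564 e and q_M = -1.1128 e. The ECS charge set is generated from
#' the PES set by scalar scaling (default factor 0.965), never typed by hand.
#'
#' @param ecs_factor charge scaling factor defining the effective charge
#'   surface
#' @return a [molecular_species()] named `"H2O"`
#' @export
#' @examples
#' w <- water_tip4p2005()
#' w$charge_sets$ECS$charges  # 0, +0.53693, +0.53693, -1.07385
water_tip4p2005 <- function(ecs_factor = 0.965) {
  r_oh <- 0.09572
  r_om <- 0.01546
  half <- (104.52 / 2) * pi / 180
  sites <- list(
    site_spec("O", lj_epsilon = 0.7749, lj_sigma = 0.31589, charge = 0,
              position = c(0, 0, 0), mass = 15.999),
    site_spec("H1", charge = 0.5564,
              position = c(r_oh * sin(half), 0, r_oh * cos(half)),
              mass = 1.008),
    site_spec("H2", charge = 0.5564,
              position = c(-r_oh * sin(half), 0, r_oh * cos(half)),
              mass = 1.008),
    site_spec("M", charge = -1.1128, position = c(0, 0, r_om), mass = 0)
  )
  molecular_species("H2O", sites, ecs_factor = ecs_factor)
}

#' Example scaled-charge NaCl ion species with ECS charges
#'
#' Single-site Na+ and Cl- ions in the scaled-charge (0.85 e) convention used
#' by the Madrid-2019 family, with the ECS ion charges +0.95/-0.95 e. LJ
#' self-parameters follow the published Madrid-2019 values; bespoke
#' ion-water cross terms are not bundled and must be supplied as a pair
#' override table (see [cross_interaction()]).
#'
#' @return list with elements `cation`, `anion`
#'   ([molecular_species()] objects) and `group` (a [fractional_group()])
#' @export
nacl_scaled_charge <- function() {
  na <- molecular_species(
    "Na+",
    list(site_spec("Na", lj_epsilon = 1.472356, lj_sigma = 0.221737,
                   charge = 0.85, mass = 22.990)),
    charge_sets = list(PES = charge_set("PES", 0.85),
                       ECS = charge_set("ECS", 0.95)),
    net_charge = 0.85)
  cl <- molecular_species(
    "Cl-",
    list(site_spec("Cl", lj_epsilon = 0.076923, lj_sigma = 0.469906,
                   charge = -0.85, mass = 35.453)),
    charge_sets = list(PES = charge_set("PES", -0.85),
                       ECS = charge_set("ECS", -0.95)),
    net_charge = -0.85)
  list(cation = na, anion = cl,
       group = fractional_group(c("Na+" = 1L, "Cl-" = 1L)))
}

#' Single-site Lennard-Jones species (test and fixture workhorse)
#'
#' @param name label
#' @param epsilon LJ well depth, kJ/mol
#' @param sigma LJ diameter, nm
#' @param charge point charge, e (same on both surfaces)
#' @param mass g/mol
#' @return a [molecular_species()]
#' @export
lj_species <- function(name = "LJ", epsilon = 1, sigma = 0.3, charge = 0,
                       mass = 40) {
  molecular_species(
    name, list(site_spec(name, lj_epsilon = epsilon, lj_sigma = sigma,
                         charge = charge, mass = mass)),
    net_charge = charge)
}
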