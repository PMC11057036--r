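# Structured-text configuration: force-field and run files, validation,
# and provenance blocks.

.known_units <- c(temperature = "K", pressure = "bar", cutoff = "nm",
                  density = "kg/m3")

# parse "300", 300 or "300 K"; reject unknown unit suffixes
.parse_quantity <- function(x, field, unit, errs) {
  if (is.numeric(x)) return(list(value = x, errs = errs))
  if (is.character(x)) {
    parts <- strsplit(trimws(x), "\\s+")[[1]]
    val <- suppressWarnings(as.numeric(parts[1]))
    if (!is.na(val) && length(parts) == 1L)
      return(list(value = val, errs = errs))
    if (!is.na(val) && length(parts) == 2L) {
      if (identical(parts[2], unit))
        return(list(value = val, errs = errs))
      return(list(value = NA_real_, errs = c(errs, sprintf(
        "%s: unknown unit suffix '%s' (expected '%s')", field, parts[2],
        unit))))
    }
  }
  list(value = NA_real_,
       errs = c(errs, sprintf("%s: not a number", field)))
}

.ff_from_config <- function(cfg, path, errs = character(0)) {
  if (is.null(cfg$species) || !length(cfg$species)) {
    errs <- c(errs, sprintf("%s: species: missing or empty", path))
    return(list(ff = NULL, errs = errs))
  }
  species <- list()
  for (i in seq_along(cfg$species)) {
    sc <- cfg$species[[i]]
    where <- sprintf("%s: species[%d]", path, i)
    if (is.null(sc$name)) {
      errs <- c(errs, paste0(where, ": name missing"))
      next
    }
    if (is.null(sc$sites) || !length(sc$sites)) {
      errs <- c(errs, paste0(where, ": sites missing"))
      next
    }
    sites <- list()
    q_ecs <- numeric(0)
    bad <- FALSE
    for (j in seq_along(sc$sites)) {
      s <- sc$sites[[j]]
      swhere <- sprintf("%s.sites[%d]", where, j)
      for (req in c("name", "sigma", "epsilon", "q_pes", "q_ecs", "xyz")) {
        if (is.null(s[[req]])) {
          errs <- c(errs, sprintf("%s: field '%s' missing", swhere, req))
          bad <- TRUE
        }
      }
      if (bad) next
      sig <- .parse_quantity(s$sigma, paste0(swhere, ".sigma"), "nm", errs)
      errs <- sig$errs
      if (is.na(sig$value)) { bad <- TRUE; next }
      sites[[j]] <- site_spec(s$name, lj_epsilon = s$epsilon,
                              lj_sigma = sig$value, charge = s$q_pes,
                              position = unlist(s$xyz),
                              mass = if (is.null(s$mass)) 0 else s$mass)
      q_ecs <- c(q_ecs, s$q_ecs)
    }
    if (bad) next
    pes <- charge_set("PES", vapply(sites, function(x) x$charge, numeric(1)))
    species[[length(species) + 1L]] <- molecular_species(
      sc$name, sites,
      charge_sets = list(PES = pes, ECS = charge_set("ECS", q_ecs)),
      net_charge = if (is.null(sc$net_charge)) NULL else sc$net_charge)
  }
  overrides <- NULL
  if (!is.null(cfg$pair_overrides)) {
    overrides <- do.call(rbind, lapply(seq_along(cfg$pair_overrides),
      function(i) {
        o <- cfg$pair_overrides[[i]]
        data.frame(site_a = o$site_a, site_b = o$site_b,
                   epsilon = o$epsilon, sigma = o$sigma)
      }))
  }
  group <- NULL
  if (!is.null(cfg$fractional_group)) {
    comp <- unlist(cfg$fractional_group$composition)
    surf <- cfg$fractional_group$surface
    if (is.null(surf)) surf <- "PES"
    if (!surf %in% c("PES", "ECS"))
      errs <- c(errs, sprintf(
        "%s: fractional_group.surface must be PES or ECS", path))
    else group <- fractional_group(comp, surf)
  }
  rc <- 0.9
  if (!is.null(cfg$cutoff)) {
    q <- .parse_quantity(cfg$cutoff, paste0(path, ": cutoff"), "nm", errs)
    errs <- q$errs
    if (!is.na(q$value)) rc <- q$value
  }
  acc <- if (is.null(cfg$ewald_accuracy)) 1e-5 else cfg$ewald_accuracy
  if (length(errs)) return(list(ff = NULL, errs = errs, group = group))
  ff <- ff_bundle(species, rc = rc, tail = !isFALSE(cfg$lj_tail),
                  ewald_accuracy = acc, overrides = overrides)
  if (!is.null(group)) {
    rep <- validate_species(species, group)
    if (!rep$pass)
      errs <- c(errs, paste0(path, ": ", rep$messages))
  }
  list(ff = ff, errs = errs, group = group)
}

.run_from_config <- function(cfg, path, errs = character(0)) {
  if (is.null(cfg$seed)) {
    errs <- c(errs, sprintf("%s: seed: mandatory field missing", path))
  }
  q <- .parse_quantity(cfg$temperature, paste0(path, ": temperature"), "K",
                       errs)
  errs <- q$errs; T <- q$value
  q <- .parse_quantity(cfg$pressure, paste0(path, ": pressure"), "bar", errs)
  errs <- q$errs; P <- q$value
  if (is.null(cfg$counts) || !length(cfg$counts))
    errs <- c(errs, sprintf("%s: counts: missing", path))
  run <- list(seed = cfg$seed, T = T, P = P,
              counts = unlist(cfg$counts),
              density = if (is.null(cfg$density)) NULL else cfg$density,
              nsteps_equil = if (is.null(cfg$nsteps_equil)) 2e4 else
                cfg$nsteps_equil,
              nsteps_prod = if (is.null(cfg$nsteps_prod)) 1e5 else
                cfg$nsteps_prod,
              nblocks = if (is.null(cfg$nblocks)) 5 else cfg$nblocks,
              move_weights = if (is.null(cfg$move_weights))
                c(0.35, 0.35, 0.02, 0.14, 0.14) else
                unlist(cfg$move_weights))
  list(run = run, errs = errs)
}

#' Load and validate force-field and run configuration files
#'
#' Reads YAML configuration files, checks the schema (required fields,
#' numeric types, known unit suffixes, mandatory seed, species invariants
#' via [validate_species()]) and returns a validated bundle. All violations
#' are collected and reported together, each prefixed with the file and
#' field path.
#'
#' @param ff_path path to the force-field file (species, sites, pair
#'   overrides, fractional group, cutoff, Ewald accuracy)
#' @param run_path optional path to the run file (seed, temperature,
#'   pressure, counts, run lengths, move weights)
#' @return list with `ff` (an [ff_bundle()]), `group`
#'   (a [fractional_group()] or NULL) and `run` (a named list or NULL)
#' @export
load_configs <- function(ff_path, run_path = NULL) {
  if (!file.exists(ff_path))
    stop("force-field config not found: ", ff_path, call. = FALSE)
  ffc <- yaml::read_yaml(ff_path)
  res <- .ff_from_config(ffc, basename(ff_path))
  errs <- res$errs
  run <- NULL
  if (!is.null(run_path)) {
    if (!file.exists(run_path))
      stop("run config not found: ", run_path, call. = FALSE)
    rc <- yaml::read_yaml(run_path)
    rres <- .run_from_config(rc, basename(run_path))
    errs <- c(errs, rres$errs)
    run <- rres$run
  }
  if (length(errs))
    stop("configuration rejected:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  list(ff = res$ff, group = res$group, run = run)
}

#' Provenance block for published outputs
#'
#' Every table the package writes carries a JSON provenance block recording
#' the inputs, constants, seeds and tolerances that produced it, so that the
#' output is reproducible from the block alone.
#'
#' @param inputs named list of inputs (configs, state points)
#' @param seed integer seed
#' @param extras named list of extra constants/tolerances
#' @return named list (serializable with jsonlite)
#' @export
provenance_block <- function(inputs = list(), seed = NA, extras = list()) {
  c(list(package = "ecsmc",
         version = as.character(utils::packageVersion("ecsmc")),
         seed = seed,
         constants = ecs_constants()),
    list(inputs = inputs), extras)
}

#' Write a CSV table with a provenance sidecar
#'
#' Tables are comma-separated with a header row, UTF-8, '.' decimal
#' separator. The provenance block is written next to the table as
#' `<name>.provenance.json`.
#'
#' @param df data.frame
#' @param path output CSV path
#' @param provenance a [provenance_block()]
#' @return `path`, invisibly
#' @export
write_table_with_provenance <- function(df, path, provenance) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  jsonlite::write_json(provenance,
                       sub("\\.csv$", ".provenance.json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
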