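# Run outputs: JSON summary, CSV block series, XYZ snapshots.

# site positions of every molecule in laboratory coordinates
.site_positions <- function(state, ff) {
  out <- list()
  for (m in seq_along(state$spid)) {
    sp <- ff$species_objects[[state$spid[m]]]
    q <- state$quat[m, ]
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- rbind(
      c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
      c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
      c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
    for (s in sp$sites) {
      out[[length(out) + 1L]] <- data.frame(
        molecule = m, species = sp$name, site = s$name,
        t(state$com[m, ] + as.vector(R %*% s$position)))
    }
  }
  df <- do.call(rbind, out)
  names(df)[4:6] <- c("x", "y", "z")
  df
}

#' Write a system snapshot in XYZ format
#'
#' Coordinates in nm (XYZ readers expecting Angstrom can rescale; the
#' comment line states the unit and box edge). Site names are used as
#' element labels for quick visual inspection.
#'
#' @param state a [build_system()] state
#' @param ff the matching [ff_bundle()]
#' @param path output file
#' @param comment second-line comment
#' @return `path`, invisibly
#' @export
write_xyz <- function(state, ff, path, comment = NULL) {
  df <- .site_positions(state, ff)
  if (is.null(comment))
    comment <- sprintf("ecsmc snapshot, units nm, box L = %.6f nm", state$L)
  lines <- c(sprintf("%d", nrow(df)), comment,
             sprintf("%-4s %12.6f %12.6f %12.6f", df$site, df$x, df$y,
                     df$z))
  writeLines(lines, path)
  invisible(path)
}

#' Write the outputs of an NPT run to a directory
#'
#' Emits `summary.json` (means, errors, acceptance rates, bias weights,
#' settings and the provenance block), `blocks.csv` (per-block density,
#' mass density, energy and volume) and `final.xyz` (snapshot of the last
#' configuration).
#'
#' @param run an [run_npt()] result
#' @param ff the [ff_bundle()] used for the run
#' @param dir output directory (created if needed)
#' @param provenance optional [provenance_block()]; a default one is built
#'   from the run settings
#' @return `dir`, invisibly
#' @export
write_run_outputs <- function(run, ff, dir, provenance = NULL) {
  stopifnot(inherits(run, "npt_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(provenance))
    provenance <- provenance_block(
      inputs = list(T = run$T, P = run$P, settings = run$settings),
      seed = run$seed)
  summary <- list(
    T = run$T, P = run$P, seed = run$seed,
    density = run$density[c("mean", "se")],
    rho_mass = run$rho_mass[c("mean", "se")],
    u = run$u[c("mean", "se")],
    acceptance = as.list(run$acceptance),
    wl_converged = run$wl_converged,
    bias_weights = run$lambda_histogram$eta,
    lambda_counts = run$lambda_histogram$counts,
    energy_drift = run$energy_drift,
    settings = run$settings,
    provenance = provenance)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  blocks <- data.frame(
    block = seq_along(run$density$blocks),
    density = run$density$blocks,
    rho_mass = run$rho_mass$blocks,
    u = run$u$blocks,
    volume = run$volume$blocks)
  write_table_with_provenance(blocks, file.path(dir, "blocks.csv"),
                              provenance)
  write_xyz(run$final_state, ff, file.path(dir, "final.xyz"))
  invisible(dir)
}
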