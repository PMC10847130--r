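#' Force report over membranes, solutes and fluxes
#'
#' Convenience sweep: evaluates [force_profile()] for every combination and
#' binds the results, the table behind the force/flux figures and the CLI
#' `forces` subcommand.
#'
#' @param membranes Named list of [membrane_spec()]s (or a single spec).
#' @param solutes Named list of [solute_spec()]s (or a single spec).
#' @param fluxes Fluxes, L m^-2 h^-1.
#' @param fluid A [fluid_state()].
#' @param model A [threshold_model()].
#' @return A `force_profile` tibble ordered by membrane, solute, flux.
#' @export
forces_report <- function(membranes = default_membranes(),
                          solutes = default_solutes(),
                          fluxes = c(6, 15, 30, 38, 57),
                          fluid = fluid_state(),
                          model = threshold_model(fluid = fluid)) {
  if (inherits(membranes, "membrane_spec")) membranes <- list(membranes)
  if (inherits(solutes, "solute_spec")) solutes <- list(solutes)
  out <- purrr::map_dfr(membranes, function(m) {
    purrr::map_dfr(solutes, function(s) {
      force_profile(m, s, sort(fluxes), fluid = fluid, model = model)
    })
  })
  class(out) <- c("force_profile", class(tibble()))
  out
}

#' Breakthrough analysis of files on disk
#'
#' Reads a total (layer + support) breakthrough file and optionally a
#' support-only file, integrates both to the evaluation volume, and
#' subtracts the support contribution. The CLI `breakthrough` subcommand is
#' a thin wrapper over this.
#'
#' @param total_path CSV path of the composite curve.
#' @param support_path Optional CSV path of the support-only curve; when
#'   absent the total result is returned with a warning.
#' @param at Evaluation volume, mL (default: end of the total curve).
#' @param sigma_rel Relative per-point concentration uncertainty.
#' @return One-row `adsorption_result` tibble.
#' @export
breakthrough_report <- function(total_path, support_path = NULL, at = NULL,
                                sigma_rel = 0.05) {
  total <- read_breakthrough(total_path)
  q_total <- specific_adsorbed_mass(total, up_to_volume = at,
                                    sigma_rel = sigma_rel)
  if (is.null(support_path)) {
    warn("No support curve given; returning the unsubtracted total adsorbed mass.")
    return(q_total)
  }
  support <- read_breakthrough(support_path)
  q_support <- specific_adsorbed_mass(support,
                                      up_to_volume = at %||%
                                        q_total$evaluation_volume,
                                      sigma_rel = sigma_rel)
  subtract_support(q_total, q_support)
}

#' Combined flux sweep report from a directory of curves
#'
#' Pairs `total_flux*.csv` with `support_flux*.csv` files (the layout
#' [write_experiment_set()] produces), runs the breakthrough analysis on
#' each pair, and joins the force model: the q-versus-drag table behind the
#' regime figures. Output is ordered by flux.
#'
#' @param dir Directory of breakthrough CSV files.
#' @param membrane,solute,fluid,model Force-model inputs (defaults: the
#'   1.7 nm nanotube membrane and E2).
#' @param at Evaluation volume, mL (default: each curve's end volume).
#' @param sigma_rel Relative concentration uncertainty.
#' @return A [regime_table()] tibble.
#' @export
combined_report <- function(dir,
                            membrane = default_membranes()$vacnt_1p7,
                            solute = default_solutes()$E2,
                            fluid = fluid_state(),
                            model = threshold_model(fluid = fluid),
                            at = NULL, sigma_rel = 0.05) {
  totals <- sort(list.files(dir, "^total_flux.*\\.csv$", full.names = TRUE))
  if (length(totals) == 0) {
    abort(sprintf("No total_flux*.csv files in '%s'.", dir),
          class = "poreforce_io_error")
  }
  results <- purrr::map_dfr(totals, function(pt) {
    ps <- sub("total_flux", "support_flux", pt)
    if (!file.exists(ps)) ps <- NULL
    breakthrough_report(pt, ps, at = at, sigma_rel = sigma_rel)
  })
  regime_table(results, membrane, solute, fluid = fluid, model = model)
}

#' Run manifest for reproducible reports
#'
#' Captures what produced an output directory: command, package version,
#' seed, config hash and input-file digests. Reruns with an identical
#' manifest reproduce identical numbers (all pipeline functions are pure in
#' their inputs and seed).
#'
#' @param command Character label of the command run.
#' @param seed Integer seed used.
#' @param config Any R object describing the configuration (hashed).
#' @param inputs Character vector of input file paths (digested).
#' @return Tibble with one row per manifest field (`field`, `value`).
#' @export
run_manifest <- function(command, seed = NA_integer_, config = NULL,
                         inputs = character()) {
  digest_file <- function(p) {
    if (!file.exists(p)) return(NA_character_)
    sprintf("size:%d,sum:%.0f", file.size(p),
            sum(as.integer(readBin(p, "raw", file.size(p)))))
  }
  cfg_hash <- if (is.null(config)) {
    NA_character_
  } else {
    paste0("chr:", sum(utf8ToInt(paste(deparse(config), collapse = ""))))
  }
  fields <- c(
    command = command,
    package = "poreforce",
    version = as.character(utils::packageVersion("poreforce")),
    seed = as.character(seed),
    config_hash = cfg_hash,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  input_fields <- setNames(vapply(inputs, digest_file, character(1)),
                           paste0("input:", basename(inputs)))
  tibble(field = names(c(fields, input_fields)),
         value = unname(c(fields, input_fields)))
}

#' Write a manifest alongside report outputs
#'
#' @param manifest Output of [run_manifest()].
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(manifest, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    as.list(setNames(manifest$value, manifest$field)),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
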