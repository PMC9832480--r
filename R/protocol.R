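#' Protocol configuration
#'
#' Bundles a named pipeline preset with every tunable threshold of the
#' analysis. Presets mirror the four desk-scale protocol shapes:
#' \describe{
#'   \item{curate-MEC}{curate a sampled ensemble (deduplicate, energy
#'     window, top-degeneracy) and report the MEC's shifts.}
#'   \item{curate-ensemble}{as above, but report the ensemble-averaged
#'     shifts over the energy window.}
#'   \item{traj-MEC}{subsample a trajectory at a fixed stride, attach
#'     energies, report the MEC's shifts.}
#'   \item{traj-ensemble}{subsample, report ensemble-averaged shifts and
#'     the two-state populations of the ring-RMSD series.}
#' }
#' Unknown configuration keys are rejected; every run logs the fully
#' resolved configuration in its manifest.
#'
#' @param preset one of the four preset names.
#' @param ... overrides of the defaults: `rmsd_threshold` (0.75 Angstrom),
#'   `energy_window` (10 kcal/mol), `top_degeneracy` (10), `stride` (500),
#'   `temperature` (300 K), `average_mode` ("simple"), `r_ref` (1.78
#'   Angstrom), `hbond_window` (1.5-2.5), `nh_pi_window` (2.9-3.6),
#'   `hbond_angle_min` (120), `seed` (1).
#' @return list of class `"protocol_config"`.
#' @export
protocol_config <- function(preset = c("curate-MEC", "curate-ensemble",
                                       "traj-MEC", "traj-ensemble"), ...) {
  preset <- match.arg(preset)
  cfg <- list(preset = preset, rmsd_threshold = 0.75, energy_window = 10,
              top_degeneracy = 10, stride = 500, temperature = 300,
              average_mode = "simple", r_ref = 1.78,
              hbond_window = c(1.5, 2.5), nh_pi_window = c(2.9, 3.6),
              hbond_angle_min = 120, seed = 1L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "protocol_config")
}

#' Read a protocol configuration from a YAML file
#'
#' @param path YAML file with a `preset` key plus any overrides accepted
#'   by [protocol_config()].
#' @return [protocol_config()].
#' @export
read_protocol_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$preset)) stop("config file must declare a `preset`")
  do.call(protocol_config, c(list(preset = y$preset),
                             y[setdiff(names(y), "preset")]))
}

#' @export
print.protocol_config <- function(x, ...) {
  cat("<protocol_config>", x$preset, "\n")
  for (k in setdiff(names(x), "preset"))
    cat(sprintf("  %-16s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  invisible(x)
}

# FNV-1a over the serialized config, for the run manifest.
config_hash <- function(cfg) {
  bytes <- utf8ToInt(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                      digits = NA))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run a named analysis protocol end to end
#'
#' Orchestrates the curation, descriptor, shift-prediction and
#' evaluation stages according to the preset in `config`. The result is
#' deterministic given the config and inputs, and carries a manifest
#' recording the resolved configuration, its hash, the seed, and
#' before/after conformer counts for every curation action.
#'
#' @param config [protocol_config()].
#' @param inputs named list. Roles by preset: `ensemble` (curate-*),
#'   `trajectory` + `energies` (traj-*; `energies` is a named vector
#'   keyed by `frame<i>` ids, optional for traj-ensemble averaging with
#'   mode "simple" over all subsampled frames), `shielding`
#'   ([shielding_table()], required to predict shifts), `experimental`
#'   ([shift_table()], optional; triggers evaluation),
#'   `ring_selection` (atom indices for the traj-ensemble state
#'   analysis; default all heavy atoms).
#' @return list of class `"protocol_result"`: `shifts` ([shift_table()]
#'   of predictions), `ensemble` (the curated/subsampled ensemble),
#'   `states` (traj-ensemble only), `report` (when experimental shifts
#'   were supplied), `manifest`.
#' @export
run_protocol <- function(config, inputs) {
  stopifnot(inherits(config, "protocol_config"))
  need <- function(role) {
    if (is.null(inputs[[role]]))
      stop("preset '", config$preset, "' requires input role '", role, "'")
    inputs[[role]]
  }
  log <- list()
  states <- NULL
  if (config$preset %in% c("curate-MEC", "curate-ensemble")) {
    ens <- need("ensemble")
    n0 <- length(ens$conformers)
    ens <- deduplicate(ens, rmsd_threshold = config$rmsd_threshold)
    log$deduplicate <- c(before = n0, after = length(ens$conformers))
    if (!anyNA(ensemble_energies(ens))) {
      n0 <- length(ens$conformers)
      ens <- energy_window_filter(ens, window = config$energy_window)
      log$energy_window <- c(before = n0, after = length(ens$conformers))
    }
    if (length(ens$conformers) > config$top_degeneracy) {
      n0 <- length(ens$conformers)
      ens <- select_top_degeneracy(ens, n = config$top_degeneracy)
      log$top_degeneracy <- c(before = n0, after = length(ens$conformers))
    }
  } else {
    traj <- need("trajectory")
    ens <- subsample_every(traj, stride = config$stride)
    log$subsample <- c(before = length(traj$frames),
                       after = length(ens$conformers))
    if (!is.null(inputs$energies)) ens <- set_energies(ens, inputs$energies)
    if (config$preset == "traj-ensemble") {
      sel <- inputs$ring_selection
      if (is.null(sel))
        sel <- which(toupper(trimws(traj$topology$element)) != "H")
      ref <- conformer(traj$topology, traj$frames[[1]],
                       conformer_id = "frame1")
      states <- tryCatch(
        classify_states(rmsd_series(traj, ref, selection = sel)),
        warning = function(w) {
          suppressWarnings(
            classify_states(rmsd_series(traj, ref, selection = sel)))
        })
    }
  }
  shifts <- NULL
  if (!is.null(inputs$shielding)) {
    per_conf <- shifts_by_conformer(inputs$shielding)
    if (config$preset %in% c("curate-MEC", "traj-MEC")) {
      mec <- minimum_energy_conformer(ens)
      hit <- per_conf[per_conf$conformer_id == mec$conformer_id, ]
      if (nrow(hit) == 0L)
        stop("shielding table has no entries for MEC '",
             mec$conformer_id, "'")
      shifts <- shift_table(data.frame(
        compound_id = ens$compound_id, proton_label = hit$atom_label,
        solvent = ens$solvent$name, delta = hit$delta,
        stringsAsFactors = FALSE))
    } else {
      window <- if (anyNA(ensemble_energies(ens))) Inf else
        config$energy_window
      if (is.infinite(window))
        for (i in seq_along(ens$conformers))
          if (is.na(ens$conformers[[i]]$energy))
            ens$conformers[[i]]$energy <- 0
      shifts <- ensemble_average_shifts(per_conf, ens, window = window,
                                        mode = config$average_mode,
                                        temperature = config$temperature)
    }
  }
  report <- NULL
  if (!is.null(inputs$experimental) && !is.null(shifts))
    report <- protocol_report(stats::setNames(list(shifts), config$preset),
                              inputs$experimental)
  manifest <- list(package = "macrochameleon",
                   version = as.character(utils::packageVersion("macrochameleon")),
                   config = unclass(config),
                   config_hash = config_hash(config),
                   seed = config$seed,
                   actions = log)
  structure(list(shifts = shifts, ensemble = ens, states = states,
                 report = report, manifest = manifest),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("<protocol_result>", x$manifest$config$preset,
      "| config", x$manifest$config_hash, "\n")
  for (a in names(x$manifest$actions))
    cat(sprintf("  %-14s %d -> %d conformers\n", a,
                x$manifest$actions[[a]]["before"],
                x$manifest$actions[[a]]["after"]))
  if (!is.null(x$states))
    cat(sprintf("  states        %.3f / %.3f\n",
                x$states$populations[1], x$states$populations[2]))
  if (!is.null(x$shifts)) {
    cat("  predicted shifts (ppm):\n")
    print(x$shifts$entries, row.names = FALSE)
  }
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
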