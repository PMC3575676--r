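#' Load a simulation configuration file
#'
#' Reads a YAML (or JSON) file with up to five sections — `network`,
#' `nonsynaptic`, `protocol`, `plasticity`, `seed` — and fills every absent
#' key with the model defaults, so an empty file yields the full default
#' configuration.  Unknown sections or keys are rejected with the list of
#' valid names; out-of-range values are rejected with the valid interval.
#'
#' @param path path to the configuration file.
#' @return List with `config` ([dg_config()]), `protocol` ([dg_protocol()])
#'   and `plasticity` (list with `rho`, `v`, `mu`, `substeps`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()

  valid_sections <- c("network", "nonsynaptic", "protocol", "plasticity", "seed")
  unknown <- setdiff(names(raw), valid_sections)
  if (length(unknown)) {
    stop(sprintf("unknown configuration section(s): %s; valid sections: %s",
                 paste(unknown, collapse = ", "),
                 paste(valid_sections, collapse = ", ")), call. = FALSE)
  }
  check_keys <- function(given, fn_formals, section) {
    unknown <- setdiff(names(given), fn_formals)
    if (length(unknown)) {
      stop(sprintf("unknown key(s) in `%s`: %s; valid keys: %s",
                   section, paste(unknown, collapse = ", "),
                   paste(fn_formals, collapse = ", ")), call. = FALSE)
    }
    given
  }

  ns_args <- check_keys(raw$nonsynaptic %||% list(),
                        names(formals(ns_params)), "nonsynaptic")
  net_args <- check_keys(raw$network %||% list(),
                         setdiff(names(formals(dg_config)), "ns"), "network")
  net_args$ns <- do.call(ns_params, ns_args)
  if (!is.null(raw$seed)) net_args$seed <- raw$seed
  config <- do.call(dg_config, net_args)

  prot_args <- check_keys(raw$protocol %||% list(),
                          names(formals(dg_protocol)), "protocol")
  protocol <- do.call(dg_protocol, prot_args)

  pl <- check_keys(raw$plasticity %||% list(),
                   c("rho", "v", "mu", "substeps"), "plasticity")
  pl$rho <- pl$rho %||% 0
  pl$v <- pl$v %||% 0
  pl$mu <- pl$mu %||% (pl$rho / 5)
  pl$substeps <- pl$substeps %||% "auto"
  if (pl$v < 0 || pl$v > 0.1) {
    stop(sprintf("`v` = %g rejected: must lie in [0, 0.1]", pl$v), call. = FALSE)
  }
  if (pl$rho < 0 || pl$rho >= 0.5) {
    stop(sprintf("`rho` = %g rejected: must lie in [0, 0.5)", pl$rho), call. = FALSE)
  }

  list(config = config, protocol = protocol, plasticity = pl)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Serialize a configuration back to YAML
#'
#' Inverse of [load_config()]: writing and re-loading reproduces identical
#' values.
#'
#' @param cfg list as returned by [load_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  network <- unclass(cfg$config)
  network$ns <- NULL
  network <- network[!vapply(network, is.null, logical(1))]
  network$n_total <- NULL; network$n_excitatory <- NULL
  out <- list(network = network,
              nonsynaptic = unclass(cfg$config$ns),
              protocol = unclass(cfg$protocol),
              plasticity = cfg$plasticity)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run manifest
#'
#' Everything needed to reproduce a run byte-for-byte: configuration and
#' protocol snapshots, the plasticity gains, the seed, and the package
#' version.
#'
#' @param sim a `dg_sim`.
#' @return A list.
#' @export
run_manifest <- function(sim) {
  cfg <- unclass(sim$config); cfg$ns <- unclass(cfg$ns)
  list(
    package = "dgnet",
    version = as.character(utils::packageVersion("dgnet")),
    seed = sim$seed,
    rho = sim$rho, v = sim$v, mu = sim$mu,
    days = sim$days, iterations = sim$iterations,
    config = cfg,
    protocol = unclass(sim$protocol)
  )
}

#' Write simulation results to disk
#'
#' Emits `activity.csv` (per-iteration mean average activity by cell type,
#' decimated), `windows.csv` (per-morphogenetic-step summaries including the
#' nine group mean connectivities), `summary.json` (detected events plus the
#' run manifest) and, optionally, the initial and final connection matrices
#' as CSV.
#'
#' @param sim a `dg_sim`.
#' @param out_dir output directory (created if missing).
#' @param decimate keep every `decimate`-th iteration of the activity trace.
#' @param matrices also write `C_init.csv` and `C_final.csv`.
#' @return The output directory, invisibly.
#' @export
write_results <- function(sim, out_dir, decimate = 10L, matrices = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  keep <- seq(1, sim$iterations, by = decimate)
  act <- data.frame(iteration = keep, sim$type_activity[keep, , drop = FALSE])
  utils::write.csv(act, file.path(out_dir, "activity.csv"), row.names = FALSE)
  utils::write.csv(sim$window, file.path(out_dir, "windows.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(manifest = run_manifest(sim),
         sica_events = sim$sica_events,
         all_events = sim$events),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  if (matrices) {
    utils::write.csv(sim$C_init, file.path(out_dir, "C_init.csv"), row.names = FALSE)
    utils::write.csv(sim$C_final, file.path(out_dir, "C_final.csv"), row.names = FALSE)
  }
  invisible(out_dir)
}

#' Build a reduced test network
#'
#' Shrinks the populations and the afferent count proportionally while
#' preserving the nine-group connectivity pattern, for fast tests: e.g.
#' `scale = 0.1` gives 10 granule cells, 1 mossy cell and 1 interneuron with
#' 3 granule-cell afferents each.
#'
#' @param scale population scale factor in `(0, 1]`.
#' @param ... further arguments passed to [dg_config()] (weights, clocks...).
#' @return List with `config` and an initial connection matrix `C` drawn
#'   from the current RNG state.
#' @export
make_test_fixture <- function(scale, ...) {
  base <- dg_config()
  ng <- max(1L, as.integer(round(base$n_granule * scale)))
  nm <- max(1L, as.integer(round(base$n_mossy * scale)))
  ni <- max(1L, as.integer(round(base$n_interneuron * scale)))
  if (ng + nm + ni < 4) {
    stop("`scale` too small: need at least 4 neurons in total", call. = FALSE)
  }
  aff <- min(ng, max(1L, as.integer(round(base$gc_afferents * scale))))
  config <- dg_config(n_granule = ng, n_mossy = nm, n_interneuron = ni,
                      gc_afferents = aff, ...)
  list(config = config, C = build_initial_connectivity(config))
}
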