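#' Run configuration: model, forcing, ensemble, sync and output settings
#'
#' A validated container assembled from YAML config files and/or direct
#' arguments. Unknown keys are rejected with their key path; omitted keys
#' take the documented defaults, so a minimal file such as
#' \preformatted{model:
#'   sigma: 0}
#' is a complete configuration. A configuration emitted with
#' [emit_config()] loads back identically.
#'
#' @param model named list of [eco_params()] arguments (rates, noise,
#'   initial conditions, \code{dt}, \code{n_steps}, \code{seed}).
#' @param forcing named list of [climate_forcing()] arguments
#'   (\code{kind}, \code{K0_star}, \code{kappa}, \code{omega} or
#'   \code{period}).
#' @param ensemble named list: \code{n_members}, \code{seed_base},
#'   \code{burn_in}.
#' @param sync named list: \code{n_bins}, \code{edge_fraction},
#'   \code{decimate}.
#' @param output named list: \code{dir}.
#' @return Object of class \code{eco_config} with elements \code{params}
#'   (an \code{eco_params}), \code{forcing} (an \code{eco_forcing}),
#'   \code{ensemble}, \code{sync} and \code{output}.
#' @export
eco_config <- function(model = list(), forcing = list(), ensemble = list(),
                       sync = list(), output = list()) {
  check_keys <- function(block, allowed, where) {
    bad <- setdiff(names(block), allowed)
    if (length(bad))
      stop("unknown configuration key(s): ",
           paste0(where, ".", bad, collapse = ", "), call. = FALSE)
    block
  }
  model <- check_keys(model, c("alpha", "lam", "mu", "eta", "sigma",
                               "weibull_shape", "weibull_scale", "rho0",
                               "c0", "K_init", "dt", "n_steps", "seed"),
                      "model")
  forcing <- check_keys(forcing, c("kind", "K0_star", "kappa", "omega",
                                   "period"), "forcing")
  ensemble <- check_keys(ensemble, c("n_members", "seed_base", "burn_in"),
                         "ensemble")
  sync <- check_keys(sync, c("n_bins", "edge_fraction", "decimate"), "sync")
  output <- check_keys(output, "dir", "output")

  f_defaults <- list(kind = "constant", K0_star = 1, kappa = 0.5,
                     omega = NULL, period = NULL)
  f_args <- modifyList(f_defaults, forcing, keep.null = TRUE)
  if (f_args$kind == "constant") f_args$kappa <- 0
  frc <- tryCatch(do.call(climate_forcing, f_args), error = function(e)
    stop("invalid 'forcing' block: ", conditionMessage(e), call. = FALSE))

  p_args <- c(model, list(K0_star = frc$K0_star, kappa = frc$kappa,
                          omega = frc$omega))
  prm <- tryCatch(do.call(eco_params, p_args), error = function(e)
    stop("invalid 'model' block: ", conditionMessage(e), call. = FALSE))

  ens <- modifyList(list(n_members = 16L, seed_base = 1L, burn_in = 0L),
                    ensemble)
  syn <- modifyList(list(n_bins = 36L, edge_fraction = 0.05,
                         decimate = FALSE), sync)
  out <- modifyList(list(dir = "."), output)
  structure(list(params = prm, forcing = frc, ensemble = ens, sync = syn,
                 output = out),
            class = "eco_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path path to a YAML file with any subset of the blocks
#'   \code{model}, \code{forcing}, \code{ensemble}, \code{sync},
#'   \code{output}; missing entries take defaults, unknown keys are
#'   rejected with their key path.
#' @return An [eco_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), c("model", "forcing", "ensemble", "sync",
                               "output"))
  if (length(bad))
    stop("unknown configuration block(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  eco_config(model = raw$model %||% list(),
             forcing = raw$forcing %||% list(),
             ensemble = raw$ensemble %||% list(),
             sync = raw$sync %||% list(),
             output = raw$output %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Flatten a config back into the plain nested-list form used on disk.
config_as_list <- function(config) {
  stopifnot(inherits(config, "eco_config"))
  p <- unclass(config$params)
  f <- unclass(config$forcing)
  list(model = p[setdiff(names(p), c("K0_star", "kappa", "omega"))],
       forcing = f,
       ensemble = config$ensemble,
       sync = config$sync,
       output = config$output)
}

#' Write a configuration to a YAML file
#'
#' The emitted file round-trips: [load_config()] on it reproduces the
#' identical configuration.
#'
#' @param config an [eco_config()] object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
emit_config <- function(config, path) {
  # precision 20 makes doubles (e.g. omega = 2*pi/10000) round-trip exactly
  yaml::write_yaml(config_as_list(config), path, precision = 20L)
  invisible(path)
}

#' Write a trajectory as CSV plus JSON metadata
#'
#' @param traj an [simulate_ecoculture()] trajectory.
#' @param csv_path output CSV path (columns
#'   \code{t, rho, c, K, K0, per_capita, xi}).
#' @param meta_path output JSON metadata path; defaults to the CSV path
#'   with extension \code{.json}. Metadata records the full parameter set,
#'   forcing, seed, package version, clipping count and a timestamp.
#' @return Invisible character vector of the two paths written.
#' @export
write_trajectory <- function(traj, csv_path,
                             meta_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(traj, "eco_trajectory"))
  write.csv(as.data.frame(traj), csv_path, row.names = FALSE)
  meta <- list(package = "ecoculture",
               version = as.character(packageVersion("ecoculture")),
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               params = unclass(attr(traj, "params")),
               forcing = unclass(attr(traj, "forcing")),
               n_clipped = attr(traj, "n_clipped"),
               n_barren = attr(traj, "n_barren"))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, meta_path))
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param csv_path trajectory CSV path.
#' @param meta_path JSON metadata path (defaults to the CSV path with
#'   extension \code{.json}); restores the parameter and forcing
#'   attributes.
#' @return An \code{eco_trajectory}.
#' @export
read_trajectory <- function(csv_path,
                            meta_path = sub("\\.csv$", ".json", csv_path)) {
  traj <- read.csv(csv_path)
  need <- c("t", "rho", "c", "K", "K0", "per_capita", "xi")
  if (!all(need %in% names(traj)))
    stop("not a trajectory CSV (missing columns: ",
         paste(setdiff(need, names(traj)), collapse = ", "), ")",
         call. = FALSE)
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    prm <- do.call(eco_params, meta$params)
    frc <- structure(meta$forcing, class = "eco_forcing")
    attr(traj, "params") <- prm
    attr(traj, "forcing") <- frc
    attr(traj, "n_clipped") <- meta$n_clipped
    attr(traj, "n_barren") <- meta$n_barren
  }
  class(traj) <- c("eco_trajectory", "data.frame")
  traj
}

#' Write run outputs with metadata and a checksum manifest
#'
#' Writes the result of a simulation, ensemble, sweep or synchronization
#' analysis into a directory: data as CSV (or JSON for sync reports),
#' configuration and provenance as \code{metadata.json}, and a
#' \code{manifest.json} listing every file with its MD5 checksum.
#' Timestamps live only in the metadata file, so re-running an identical
#' configuration reproduces byte-identical data files.
#'
#' @param results an \code{eco_trajectory}, \code{eco_ensemble},
#'   \code{eco_sweep} or \code{eco_sync_report}.
#' @param config the [eco_config()] that produced them.
#' @param out_dir output directory (created if needed).
#' @return Invisible named list: paths of the written files.
#' @export
write_outputs <- function(results, config, out_dir) {
  stopifnot(inherits(config, "eco_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (inherits(results, "eco_trajectory")) {
    csv <- file.path(out_dir, "trajectory.csv")
    write.csv(as.data.frame(results), csv, row.names = FALSE)
    files <- c(files, trajectory = csv)
  } else if (inherits(results, "eco_ensemble")) {
    csv <- file.path(out_dir, "ensemble_members.csv")
    write.csv(results$per_member_means, csv, row.names = FALSE)
    pooled <- file.path(out_dir, "ensemble_summary.csv")
    write.csv(data.frame(E_rho = results$E_rho, E_c = results$E_c,
                         E_K = results$E_K, n_members = results$n_members,
                         n_steps = results$n_steps,
                         burn_in = results$burn_in),
              pooled, row.names = FALSE)
    files <- c(files, members = csv, summary = pooled)
  } else if (inherits(results, "eco_sweep")) {
    csv <- file.path(out_dir, "sweep.csv")
    write.csv(as.data.frame(results), csv, row.names = FALSE)
    files <- c(files, sweep = csv)
  } else if (inherits(results, "eco_sync_report")) {
    rep <- lapply(results, function(r)
      list(variable = r$variable_name, rel_std_pct = r$rel_std_pct,
           ks_statistic = r$ks_statistic, ks_pvalue = r$ks_pvalue,
           n_bins = r$n_bins,
           edge_fraction_discarded = r$edge_fraction_discarded,
           decimation_stride = r$decimation_stride))
    jpath <- file.path(out_dir, "sync_report.json")
    jsonlite::write_json(rep, jpath, auto_unbox = TRUE, digits = NA)
    hists <- do.call(rbind, lapply(results, function(r)
      data.frame(variable = r$variable_name,
                 bin_lo = r$histogram$edges[-(r$n_bins + 1L)],
                 bin_hi = r$histogram$edges[-1L],
                 prob = r$histogram$prob)))
    hcsv <- file.path(out_dir, "sync_histograms.csv")
    write.csv(hists, hcsv, row.names = FALSE)
    files <- c(files, report = jpath, histograms = hcsv)
  } else {
    stop("unsupported results object of class ",
         paste(class(results), collapse = "/"), call. = FALSE)
  }
  meta_path <- file.path(out_dir, "metadata.json")
  meta <- list(package = "ecoculture",
               version = as.character(packageVersion("ecoculture")),
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               config = config_as_list(config),
               result_class = class(results)[1])
  if (inherits(results, "eco_trajectory")) {
    meta$n_clipped <- attr(results, "n_clipped")
    meta$n_barren <- attr(results, "n_barren")
  }
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  manifest_path <- file.path(out_dir, "manifest.json")
  sums <- tools::md5sum(unname(c(files, metadata = meta_path)))
  manifest <- lapply(seq_along(sums), function(i)
    list(file = basename(names(sums)[i]), md5 = unname(sums[i])))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  invisible(as.list(c(files, metadata = meta_path,
                      manifest = manifest_path)))
}
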