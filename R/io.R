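# Configuration files, trajectory export, and run manifests.
#
# Configs are flat YAML: a `scenario` block, a `parameters` block (one key
# per model constant), and a `metadata` block recording units and
# provenance. Trajectories export either as an RDS container (bit-exact
# round-trip) or as long-format delimited text (time, radius, field,
# value; lossless shortest-representation doubles).

.scenario_keys <- c("name", "injury_radius", "injury_density", "C0", "U0",
                    "horizon", "r_max", "n_nodes", "out_dt")

#' Write a scenario configuration file
#'
#' @param spec A [scenario_spec()].
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  pt <- param_table(spec$params)
  cfg <- list(
    scenario = stats::setNames(lapply(.scenario_keys, function(k) spec[[k]]),
                               .scenario_keys),
    parameters = stats::setNames(as.list(pt$value), pt$name),
    metadata = list(
      units = stats::setNames(as.list(pt$unit), pt$name),
      provenance = stats::setNames(as.list(pt$provenance), pt$name),
      h_sharpness = spec$params$h_sharpness,
      notes = paste("time in hours, space in mm, densities in cells/mm^2;",
                    "all calibrated values are implementer choices, not",
                    "experimentally determined")
    )
  )
  # YAML has no Inf literal guaranteed portable; serialize as string
  cfg$parameters <- lapply(cfg$parameters, function(v) {
    if (is.infinite(v)) ".inf" else v
  })
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Load and validate a scenario configuration
#'
#' Unknown keys are rejected with their names; missing keys are filled
#' from the documented defaults with a notice; invariant violations are
#' reported with the parameter name and bound.
#'
#' @param path Path to a YAML config written by [write_scenario_config()]
#'   (or by hand to the same schema).
#' @param quiet Suppress the filled-from-default notices.
#' @return A [scenario_spec()] (its `params` element is the parameter set).
#' @export
read_scenario_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  bad_top <- setdiff(names(cfg), c("scenario", "parameters", "metadata"))
  if (length(bad_top) > 0) {
    stop("unknown top-level config section(s): ",
         paste(bad_top, collapse = ", "), call. = FALSE)
  }
  sc <- cfg$scenario %||% list()
  bad <- setdiff(names(sc), .scenario_keys)
  if (length(bad) > 0) {
    stop("unknown scenario key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  missing_sc <- setdiff(.scenario_keys, names(sc))
  if (length(missing_sc) > 0 && !quiet) {
    message("scenario key(s) filled from defaults: ",
            paste(missing_sc, collapse = ", "))
  }
  pv <- cfg$parameters %||% list()
  bad <- setdiff(names(pv), .param_names())
  if (length(bad) > 0) {
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  missing_pv <- setdiff(.param_names(), names(pv))
  if (length(missing_pv) > 0 && !quiet) {
    message("parameter(s) filled from reference defaults: ",
            paste(missing_pv, collapse = ", "))
  }
  pv <- lapply(pv, function(v) if (identical(v, ".inf")) Inf else v)
  hs <- cfg$metadata$h_sharpness %||% 0
  params <- do.call(chondro_params, c(pv, list(h_sharpness = hs)))
  args <- c(sc, list(params = params))
  do.call(scenario_spec, args)
}

#' Hash of a scenario configuration
#'
#' Stable content hash of the scenario settings and parameter values,
#' recorded in manifests and export headers so outputs can be traced to
#' their configuration.
#'
#' @param spec A [scenario_spec()].
#' @return A character hash.
#' @export
config_hash <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  pt <- param_table(spec$params)
  rlang::hash(list(
    scenario = lapply(.scenario_keys, function(k) spec[[k]]),
    parameters = pt$value,
    h_sharpness = spec$params$h_sharpness
  ))
}

#' Build a run manifest
#'
#' Provenance record for a finished run: scenario name, config hash,
#' package version, grid and tolerance settings, solver step diagnostics,
#' and the output file inventory.
#'
#' @param traj A `chondro_trajectory` (with an attached scenario spec).
#' @param files Character vector of output files the run produced.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(traj, files = character(0)) {
  stopifnot(inherits(traj, "chondro_trajectory"))
  spec <- attr(traj, "spec")
  structure(list(
    scenario = if (!is.null(spec)) spec$name else NA_character_,
    config_hash = if (!is.null(spec)) config_hash(spec) else NA_character_,
    package_version = as.character(utils::packageVersion("chondrosim")),
    grid = list(r_max = traj$grid$r_max, n_nodes = traj$grid$n_nodes),
    solver = traj$solver,
    diagnostics = traj$diagnostics,
    horizon = max(traj$times),
    files = as.list(files)
  ), class = "run_manifest")
}

#' Write / read a run manifest (JSON)
#'
#' @param manifest A [run_manifest()].
#' @param path JSON path.
#' @return `path` / the manifest list.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "run_manifest")
}

#' Export a trajectory
#'
#' `format = "rds"` (default) writes a self-describing container (all
#' arrays, grid, parameters, provenance) whose round-trip is bit-exact.
#' `format = "csv"` writes the long-format text table
#' `time, radius, field, value` preceded by `#`-prefixed header lines
#' (grid, manifest hash), round-tripping to full double precision.
#'
#' @param traj A `chondro_trajectory`.
#' @param path Output path.
#' @param format `"rds"` or `"csv"`.
#' @param fields Fields to export (default all ten).
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(traj, path, format = c("rds", "csv"),
                              fields = CHONDRO_FIELDS) {
  stopifnot(inherits(traj, "chondro_trajectory"))
  format <- match.arg(format)
  fields <- match.arg(fields, CHONDRO_FIELDS, several.ok = TRUE)
  spec <- attr(traj, "spec")
  hash <- if (!is.null(spec)) config_hash(spec) else NA_character_
  if (format == "rds") {
    obj <- list(
      times = traj$times,
      states = traj$states[, fields, , drop = FALSE],
      fields = fields,
      grid = traj$grid, params = unclass(traj$params),
      solver = traj$solver, diagnostics = traj$diagnostics,
      config_hash = hash,
      package_version = as.character(utils::packageVersion("chondrosim"))
    )
    saveRDS(obj, path)
  } else {
    long <- tidy_trajectory(traj, fields = fields)
    header <- c(
      paste0("# chondrosim trajectory v",
             utils::packageVersion("chondrosim")),
      paste0("# config_hash: ", hash),
      paste0("# r_max_mm: ", traj$grid$r_max),
      paste0("# n_nodes: ", traj$grid$n_nodes),
      paste0("# fields: ", paste(fields, collapse = ",")),
      paste0("# node_centers_mm: ",
             paste(format(traj$grid$node_centers, digits = 17),
                   collapse = ","))
    )
    writeLines(header, path)
    readr::write_csv(long, path, append = TRUE, col_names = TRUE)
  }
  invisible(path)
}

#' Read back an exported trajectory
#'
#' @param path File written by [export_trajectory()].
#' @param format `"rds"` or `"csv"` (guessed from the extension by default).
#' @return For `"rds"`, the container list; for `"csv"`, the long tibble
#'   with the header metadata in attribute `"header"`.
#' @export
read_trajectory <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "csv"
  }
  if (format == "rds") return(readRDS(path))
  lines <- readLines(path, n = 50)
  header <- lines[startsWith(lines, "#")]
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  attr(out, "header") <- header
  out
}

#' Export a lesion summary as delimited text
#'
#' One row per output time, with the regime label and configuration hash
#' in `#`-prefixed metadata lines.
#'
#' @param summary A [lesion_summary()] tibble.
#' @param path Output path.
#' @param regime Optional regime label to record.
#' @param hash Optional config hash to record.
#' @return `path`, invisibly.
#' @export
export_summary <- function(summary, path, regime = NULL, hash = NULL) {
  header <- c(
    paste0("# chondrosim lesion summary v",
           utils::packageVersion("chondrosim")),
    if (!is.null(hash)) paste0("# config_hash: ", hash),
    if (!is.null(regime)) paste0("# regime: ", regime)
  )
  writeLines(header, path)
  readr::write_csv(summary, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
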