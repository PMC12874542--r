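# Readers, writers, configuration, and run reports.
#
# Particle tables and refractometry series travel as plain CSV with fixed
# column schemas; analysis configuration is a single YAML document with a
# strictly validated set of blocks; reports are JSON with units encoded
# in key names.

PARTICLE_COLS <- c("run_id", "condition", "d_um", "n", "sigma_d_um", "sigma_n")
REFRACTOMETRY_COLS <- c("mw_kda", "concentration", "concentration_unit",
                        "n_measured")

#' Read a per-particle characterization table
#'
#' Reads a CSV with columns `run_id`, `condition`, `d_um`, `n`,
#' `sigma_d_um`, `sigma_n`. Rows violating the record invariants
#' (diameter outside the 0.5-10 um instrument range, index <= 1,
#' negative or missing uncertainties) are rejected with row-numbered
#' diagnostics.
#'
#' @param path CSV file path.
#' @return a validated particle table (data frame).
#' @export
read_particle_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PARTICLE_COLS, names(df))
  if (length(missing_cols))
    stop("particle table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) stop("particle table is empty", call. = FALSE)
  validate_particles(df)
}

validate_particles <- function(df) {
  bad <- !is.finite(df$d_um) | df$d_um < 0.5 | df$d_um > 10 |
    !is.finite(df$n) | df$n <= 1 |
    !is.finite(df$sigma_d_um) | df$sigma_d_um < 0 |
    !is.finite(df$sigma_n) | df$sigma_n < 0
  if (any(bad)) {
    message(sum(bad), " malformed particle row(s) rejected (rows ",
            paste(utils::head(which(bad), 10), collapse = ", "),
            if (sum(bad) > 10) ", ..." else "", ")")
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no valid particle rows remain", call. = FALSE)
  rownames(df) <- NULL
  df
}

#' Write a particle table to CSV
#'
#' @param records particle table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_particle_table <- function(records, path) {
  stopifnot(all(PARTICLE_COLS %in% names(records)))
  utils::write.csv(records[, intersect(c(PARTICLE_COLS, "true_population"),
                                       names(records)), drop = FALSE],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a refractometry series from CSV
#'
#' Expects columns `mw_kda`, `concentration`, `concentration_unit`,
#' `n_measured`.
#'
#' @param path CSV file path.
#' @return a readings data frame for [series_to_phi].
#' @export
read_refractometry_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(REFRACTOMETRY_COLS, names(df))
  if (length(missing_cols))
    stop("refractometry table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) stop("refractometry table is empty", call. = FALSE)
  df
}

# ---- configuration -------------------------------------------------------

CONFIG_BLOCKS <- c("optics", "brush", "pipeline", "seeds")

#' Read and validate an analysis configuration
#'
#' The configuration is one YAML document with up to four blocks:
#' \describe{
#'   \item{optics}{named sub-blocks, one per bead type, each with `n0`,
#'     `nm`, `n1` and optional `sigma_*`; parsed into
#'     [optical_constants].}
#'   \item{brush}{`mw_coat`, `v_s`, and optional `monomer_mass`,
#'     `increment`, `r_g`, `m_ps`, `rho_ps`; parsed into
#'     [brush_parameters].}
#'   \item{pipeline}{`gates` (name -> d_min, d_max, n_min, n_max),
#'     `alpha`, `threshold_k`, `reference`, `ground_truth_d`,
#'     `n_c_layer`.}
#'   \item{seeds}{named integer seeds for every stochastic stage.}
#' }
#' Unknown top-level keys are rejected so typos cannot silently disable
#' a setting.
#'
#' @param path YAML file path.
#' @return a list with parsed `optics` (named list of
#'   [optical_constants]), `brush` ([brush_parameters] or NULL),
#'   `pipeline`, `seeds`, and the config file `digest`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), CONFIG_BLOCKS)
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  optics <- NULL
  if (!is.null(raw$optics)) {
    optics <- lapply(raw$optics, function(b) {
      do.call(optical_constants, b[intersect(names(b),
        c("n0", "nm", "n1", "sigma_n0", "sigma_nm", "sigma_n1"))])
    })
  }
  brush <- NULL
  if (!is.null(raw$brush)) {
    brush <- do.call(brush_parameters, raw$brush[intersect(names(raw$brush),
      c("mw_coat", "monomer_mass", "increment", "l", "r_g",
        "m_ps", "rho_ps", "v_s"))])
  }
  pipeline <- raw$pipeline
  if (!is.null(pipeline$gates)) {
    pipeline$gates <- lapply(names(pipeline$gates), function(nm) {
      g <- pipeline$gates[[nm]]
      population_gate(nm, g$d_min, g$d_max, g$n_min, g$n_max)
    })
  }
  list(optics = optics, brush = brush, pipeline = pipeline,
       seeds = raw$seeds, digest = unname(tools::md5sum(path)))
}

# ---- reports -------------------------------------------------------------

#' Assemble a reproducible run report
#'
#' Bundles stage outputs with the package version, the config digest,
#' input-file digests, and the seed registry, so every reported number is
#' traceable to a stage, a configuration, and a seed.
#'
#' @param stage name of the pipeline stage ("graft", "dvdm", "assay",
#'   "simulate").
#' @param outputs named list of stage outputs (coerced to JSON-friendly
#'   forms; keys should carry units, e.g. `delta_dp_nm`).
#' @param config parsed config (from [read_analysis_config]) or NULL.
#' @param input_paths character vector of input files to digest.
#' @param seeds named list of seeds used.
#' @return a list of class `run_report`.
#' @export
build_run_report <- function(stage, outputs, config = NULL,
                             input_paths = character(), seeds = NULL) {
  digests <- if (length(input_paths))
    as.list(tools::md5sum(input_paths)) else list()
  structure(list(
    stage = stage,
    package_version = as.character(utils::packageVersion("holoassay")),
    config_digest = if (is.null(config)) NULL else config$digest,
    input_digests = digests,
    seeds = seeds,
    outputs = outputs), class = "run_report")
}

#' Write a run report as JSON
#'
#' @param report a `run_report` (or any list).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE, null = "null")
  invisible(path)
}

#' Flatten a coating solution for reporting
#'
#' @param sol a `coating_solution`.
#' @return a named list with unit-suffixed keys.
#' @export
coating_solution_report <- function(sol) {
  stopifnot(inherits(sol, "coating_solution"))
  list(gamma_c_nm2 = sol$gamma_c,
       sigma_gamma_c_nm2 = sol$sigma_gamma_c,
       a_c_nm = sol$a_c, sigma_a_c_nm = sol$sigma_a_c,
       phi_c = sol$phi_c, n_c = sol$n_c,
       x_nm = sol$x, delta_d0_nm = sol$delta_d0,
       delta_dp_measured_nm = sol$delta_d_measured,
       uncertainty_method = if (is.null(sol$method)) "none" else sol$method)
}
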