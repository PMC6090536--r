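#' Simulation specification
#'
#' Aggregates every model parameter for a batch run, with the defaults
#' used throughout the package: temporal boundary three times the
#' criterion, width/peak proportionality cv = 0.2, learning offset
#' epsilon = 0.5 s, unit initial weights. Either a uniform population
#' (`n_cells`) or one of the packaged fixtures (`fixture`) supplies the
#' cells. All fields are validated before any computation.
#'
#' @param criterion criterion time(s) in seconds; `run_simulate` and
#'   `run_lesion` use the first, `run_scalar` needs at least two.
#' @param n_cells number of cells for a uniform population (ignored when
#'   `fixture` is given).
#' @param fixture optional fixture name per [make_fixture_population].
#' @param boundary_factor,cv population parameters.
#' @param epsilon,n_trials,initial_weight learning parameters.
#' @param lesion optional `list(side =, fraction =)` applied after
#'   training by [run_lesion].
#' @param grid_step grid spacing in seconds; default `criterion/1000`.
#' @param seed integer recorded in the manifest. The model itself is
#'   deterministic; the seed exists so downstream stochastic extensions
#'   and run manifests share one reproducibility convention.
#' @return An object of class `simulation_spec`.
#' @examples
#' simulation_spec(criterion = 10, fixture = "fig2_T10", n_trials = 2)
#' @export
simulation_spec <- function(criterion, n_cells = 100, fixture = NULL,
                            boundary_factor = 3, cv = 0.2, epsilon = 0.5,
                            n_trials = 1L, initial_weight = 1, lesion = NULL,
                            grid_step = NULL, seed = 1L) {
  if (!is.numeric(criterion) || length(criterion) < 1L ||
      any(!is.finite(criterion)) || any(criterion <= 0))
    stop("'criterion' must be one or more positive numbers", call. = FALSE)
  if (!is.null(fixture))
    fixture <- match.arg(fixture, c("fig2_T10", "fig2_T30", "sparse_T10"))
  # constructors re-validate; building them here fails fast on a bad spec
  if (is.null(fixture))
    invisible(make_uniform_population(criterion[1L], n_cells, boundary_factor, cv))
  cfg <- learning_config(criterion[1L], epsilon, n_trials, initial_weight)
  if (!is.null(lesion)) {
    if (!is.list(lesion) || is.null(lesion$side) || is.null(lesion$fraction))
      stop("'lesion' must be list(side =, fraction =)", call. = FALSE)
    lesion$side <- match.arg(lesion$side, c("ventral", "dorsal"))
    if (!is.numeric(lesion$fraction) || lesion$fraction < 0 || lesion$fraction > 1)
      stop("lesion fraction must be in [0, 1]", call. = FALSE)
  }
  if (is.null(grid_step)) grid_step <- criterion[1L] / 1000
  if (!is.numeric(grid_step) || grid_step <= 0)
    stop("'grid_step' must be > 0", call. = FALSE)
  structure(list(criterion = as.numeric(criterion), n_cells = n_cells,
                 fixture = fixture, boundary_factor = boundary_factor, cv = cv,
                 epsilon = cfg$epsilon, n_trials = cfg$n_trials,
                 initial_weight = cfg$initial_weight, lesion = lesion,
                 grid_step = as.numeric(grid_step), seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Read a simulation spec from a JSON config file
#'
#' The JSON object mirrors the [simulation_spec] field names; `overrides`
#' (typically parsed CLI flags) take precedence over file values.
#'
#' @param path JSON file path.
#' @param overrides named list of fields replacing file values.
#' @return A validated `simulation_spec`.
#' @export
read_simulation_spec <- function(path, overrides = list()) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(simulation_spec))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  raw[names(overrides)] <- overrides
  if (!is.null(raw$lesion)) raw$lesion <- as.list(raw$lesion)
  do.call(simulation_spec, raw)
}

build_population <- function(spec) {
  if (!is.null(spec$fixture))
    make_fixture_population(spec$fixture, cv = spec$cv)
  else
    make_uniform_population(spec$criterion[1L], spec$n_cells,
                            spec$boundary_factor, spec$cv)
}

spec_grid <- function(spec, boundary = NULL) {
  if (is.null(boundary)) {
    boundary <- if (!is.null(spec$fixture))
      attr(build_population(spec), "boundary")
    else spec$boundary_factor * spec$criterion[1L]
  }
  time_grid(0, boundary, spec$grid_step)
}

write_manifest <- function(spec, path) {
  manifest <- c(unclass(spec),
                list(package = "timecellmap",
                     package_version =
                       as.character(utils::packageVersion("timecellmap"))))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Run a single-criterion simulation and write its artifacts
#'
#' Builds the population, trains it toward `spec$criterion[1]`, computes
#' the average time field and its width report, and writes four files to
#' `out_dir`: `weights.csv` (per-trial weight history), `field.csv`
#' (sampled field), `width_report.json`, and `manifest.json` (all
#' parameters plus the package version, sufficient to reproduce the run).
#' Outputs are deterministic: the same spec yields byte-identical files.
#'
#' @param spec a [simulation_spec].
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with `population`, `history`, `field`,
#'   `width_report`, and `paths` of the written files.
#' @examples
#' spec <- simulation_spec(criterion = 10, fixture = "fig2_T10", n_trials = 2)
#' res <- run_simulate(spec, out_dir = tempfile())
#' res$width_report
#' @export
run_simulate <- function(spec, out_dir) {
  stopifnot(inherits(spec, "simulation_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pop <- build_population(spec)
  cfg <- learning_config(spec$criterion[1L], spec$epsilon, spec$n_trials,
                         spec$initial_weight)
  fit <- train(pop, cfg)
  field <- average_time_field(fit$population, spec_grid(spec))
  report <- measure_width(field)
  paths <- list(weights = file.path(out_dir, "weights.csv"),
                field = file.path(out_dir, "field.csv"),
                width_report = file.path(out_dir, "width_report.json"),
                manifest = file.path(out_dir, "manifest.json"))
  write_weight_history(fit, paths$weights)
  write_time_field(field, paths$field)
  write_width_report(report, paths$width_report)
  write_manifest(spec, paths$manifest)
  invisible(list(population = fit$population, history = fit$history,
                 field = field, width_report = report, paths = paths))
}

#' Run the scalar-property analysis for a list of criteria
#'
#' Thin orchestration over [scalar_report]: one uniform-population run
#' per criterion with the same relative configuration, plus a JSON
#' report and manifest in `out_dir`.
#'
#' @param spec a [simulation_spec] whose `criterion` holds >= 2 values.
#' @param out_dir output directory.
#' @param scale_epsilon passed to [scalar_report].
#' @return Invisibly, a list with the `scalar_report` and file `paths`.
#' @export
run_scalar <- function(spec, out_dir, scale_epsilon = FALSE) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (length(spec$criterion) < 2L)
    stop("scalar analysis needs at least two criterion times", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- scalar_report(spec$criterion, n_cells = spec$n_cells,
                          boundary_factor = spec$boundary_factor, cv = spec$cv,
                          epsilon = spec$epsilon, n_trials = spec$n_trials,
                          scale_epsilon = scale_epsilon)
  paths <- list(scalar_report = file.path(out_dir, "scalar_report.json"),
                manifest = file.path(out_dir, "manifest.json"))
  write_scalar_report(report, paths$scalar_report)
  write_manifest(spec, paths$manifest)
  invisible(list(scalar_report = report, paths = paths))
}

#' Run a lesion experiment
#'
#' Trains the population, measures the field peak, applies the lesion
#' from `spec$lesion`, re-measures, and reports the signed peak shift
#' (post minus pre). Dorsal lesions remove the longest-duration cells
#' and shift the peak leftward (negative shift); ventral lesions remove
#' the shortest-duration cells and shift it rightward.
#'
#' @param spec a [simulation_spec] with a non-NULL `lesion` field.
#' @param out_dir output directory.
#' @return Invisibly, a list with `pre` and `post` width reports,
#'   `peak_shift` in seconds, and file `paths`.
#' @examples
#' spec <- simulation_spec(criterion = 10, n_cells = 30,
#'                         lesion = list(side = "dorsal", fraction = 0.4))
#' res <- run_lesion(spec, out_dir = tempfile())
#' res$peak_shift
#' @export
run_lesion <- function(spec, out_dir) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (is.null(spec$lesion))
    stop("spec has no lesion field", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pop <- build_population(spec)
  cfg <- learning_config(spec$criterion[1L], spec$epsilon, spec$n_trials,
                         spec$initial_weight)
  trained <- train(pop, cfg)$population
  grid <- spec_grid(spec)
  pre <- measure_width(average_time_field(trained, grid))
  lesioned <- lesion(trained, spec$lesion$side, spec$lesion$fraction)
  if (nrow(lesioned) == 0L)
    stop("lesion removed every cell; no field to measure", call. = FALSE)
  post <- measure_width(average_time_field(lesioned, grid))
  shift <- post$peak_time - pre$peak_time
  paths <- list(lesion_report = file.path(out_dir, "lesion_report.json"),
                manifest = file.path(out_dir, "manifest.json"))
  jsonlite::write_json(list(pre = unclass(pre), post = unclass(post),
                            peak_shift_s = shift,
                            side = spec$lesion$side,
                            fraction = spec$lesion$fraction),
                       paths$lesion_report, auto_unbox = TRUE, digits = NA,
                       na = "null")
  write_manifest(spec, paths$manifest)
  invisible(list(pre = pre, post = post, peak_shift = shift, paths = paths))
}
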