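#' Uniform time grid
#'
#' Sampling support for the (continuous) average time field. Analysis
#' grids should resolve the structure they measure: the constructor
#' insists on at least 100 steps across the range.
#'
#' @param start,stop grid limits in seconds, `start < stop`.
#' @param step grid spacing in seconds, > 0 and <= (stop - start)/100.
#' @return An object of class `time_grid` with elements `start`, `stop`,
#'   `step` and the sampled `times`.
#' @examples
#' time_grid(0, 30, 0.01)
#' @export
time_grid <- function(start, stop, step) {
  if (!is.numeric(start) || !is.numeric(stop) || !is.numeric(step) ||
      length(start) != 1L || length(stop) != 1L || length(step) != 1L ||
      !all(is.finite(c(start, stop, step))))
    stop("'start', 'stop' and 'step' must be single finite numbers", call. = FALSE)
  if (start >= stop) stop("'start' must be < 'stop'", call. = FALSE)
  if (step <= 0) stop("'step' must be > 0", call. = FALSE)
  if (step > (stop - start) / 100)
    stop("'step' too coarse: need at least 100 steps across the grid", call. = FALSE)
  structure(list(start = as.numeric(start), stop = as.numeric(stop),
                 step = as.numeric(step),
                 times = seq(start, stop, by = step)),
            class = "time_grid")
}

#' Default analysis grid for a criterion time
#'
#' Step `criterion/1000` over `[0, boundary]`: a relative peak-location
#' resolution of about 0.1% of the timed duration at negligible cost.
#'
#' @param criterion criterion time in seconds.
#' @param boundary upper grid limit in seconds; default `3 * criterion`.
#' @return A [time_grid].
#' @export
default_grid <- function(criterion, boundary = 3 * criterion) {
  time_grid(0, boundary, criterion / 1000)
}

#' Average time field of a population
#'
#' The population readout: the weighted sum of all cells' Gaussian
#' tuning curves,
#' \eqn{a(t) = \sum_k A_k \exp(-(t - t_k)^2 / (2 \sigma_k^2))},
#' sampled on a grid. After learning, its peak approximates the
#' criterion time. The field is linear in the weights.
#'
#' @param pop a non-empty [time_cell_population].
#' @param grid a [time_grid].
#' @return An object of class `time_field` with elements `grid` and
#'   `values` (non-negative amplitudes, one per grid point).
#' @examples
#' pop <- make_fixture_population("fig2_T10")
#' trained <- train(pop, learning_config(10))$population
#' field <- average_time_field(trained, default_grid(10))
#' @export
average_time_field <- function(pop, grid) {
  stopifnot(inherits(pop, "time_cell_population"), inherits(grid, "time_grid"))
  if (nrow(pop) == 0L)
    stop("cannot compute the field of an empty population", call. = FALSE)
  values <- as.numeric(firing_rate(pop, grid$times) %*% rep(1, nrow(pop)))
  structure(list(grid = grid, values = values), class = "time_field")
}

#' @export
print.time_field <- function(x, ...) {
  i <- which.max(x$values)
  cat(sprintf("Time field on [%g, %g] s (step %g): peak %.4g at t = %.4g s\n",
              x$grid$start, x$grid$stop, x$grid$step, x$values[i],
              x$grid$times[i]))
  invisible(x)
}

#' Plot a time field
#'
#' @param x a `time_field`.
#' @param ... passed to [graphics::plot].
#' @export
plot.time_field <- function(x, ...) {
  graphics::plot(x$grid$times, x$values, type = "l",
                 xlab = "time (s)", ylab = "amplitude", ...)
  invisible(x)
}

#' Measure peak and half-widths of a time field
#'
#' Locates the field maximum (ties broken toward the smaller time) and
#' the half-maximum crossings on either side, linearly interpolated
#' between grid samples. Half-widths are one-sided distances from the
#' peak to the crossing; the mean of the defined sides summarizes the
#' spread. A side on which the field never drops to half maximum inside
#' the grid is reported as `NA`.
#'
#' @param field a `time_field` from [average_time_field].
#' @return A list of class `width_report`: `peak_time`, `peak_value`,
#'   `half_width_left`, `half_width_right`, `half_width_mean`.
#' @examples
#' pop <- time_cell_population(10, sigma = 2)
#' measure_width(average_time_field(pop, time_grid(0, 30, 0.01)))
#' @export
measure_width <- function(field) {
  stopifnot(inherits(field, "time_field"))
  v <- field$values
  t <- field$grid$times
  if (diff(range(v)) == 0)
    stop("degenerate (constant) field: no measurable peak", call. = FALSE)
  i_peak <- which.max(v)           # which.max takes the first = smallest time
  peak_time <- t[i_peak]
  peak_value <- v[i_peak]
  half <- peak_value / 2

  cross_left <- function() {
    for (i in seq.int(i_peak, 2L)) {
      if (v[i - 1L] < half && v[i] >= half) {
        frac <- (half - v[i - 1L]) / (v[i] - v[i - 1L])
        return(peak_time - (t[i - 1L] + frac * (t[i] - t[i - 1L])))
      }
    }
    NA_real_
  }
  cross_right <- function() {
    n <- length(v)
    if (i_peak == n) return(NA_real_)
    for (i in seq.int(i_peak, n - 1L)) {
      if (v[i] >= half && v[i + 1L] < half) {
        frac <- (v[i] - half) / (v[i] - v[i + 1L])
        return(t[i] + frac * (t[i + 1L] - t[i]) - peak_time)
      }
    }
    NA_real_
  }
  hw_l <- if (i_peak == 1L) NA_real_ else cross_left()
  hw_r <- cross_right()
  if (is.na(hw_l) && is.na(hw_r))
    stop("field never drops to half maximum inside the grid", call. = FALSE)
  structure(list(peak_time = peak_time, peak_value = peak_value,
                 half_width_left = hw_l, half_width_right = hw_r,
                 half_width_mean = mean(c(hw_l, hw_r), na.rm = TRUE)),
            class = "width_report")
}

#' @export
print.width_report <- function(x, ...) {
  cat(sprintf("Peak %.4g at t = %.4g s; half-widths L %.4g / R %.4g (mean %.4g) s\n",
              x$peak_value, x$peak_time, x$half_width_left, x$half_width_right,
              x$half_width_mean))
  invisible(x)
}

#' Intrinsic half-width of one Gaussian time field
#'
#' The distance from a cell's peak at which its tuning curve falls to
#' half maximum: sigma * sqrt(2 ln 2).
#'
#' @param sigma Gaussian width in seconds, > 0 (vectorized).
#' @return Half-width in seconds.
#' @examples
#' width_cell(2)
#' @export
width_cell <- function(sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("'sigma' must be > 0", call. = FALSE)
  sigma * sqrt(2 * log(2))
}

#' Half-width of the learned weight profile
#'
#' After one trial the weight profile over peak time is
#' 1/(|T - t| + epsilon), with maximum 1/epsilon at the criterion. It
#' falls to half that maximum at distance epsilon, so the learning
#' rule's own contribution to the field width equals epsilon.
#'
#' @param epsilon regularizing offset in seconds, > 0 (vectorized).
#' @return Half-width in seconds (equal to `epsilon`).
#' @examples
#' width_learn(0.5)
#' @export
width_learn <- function(epsilon) {
  if (any(!is.finite(epsilon)) || any(epsilon <= 0))
    stop("'epsilon' must be > 0", call. = FALSE)
  epsilon
}

#' Which mechanism limits the width of the average field?
#'
#' The field width has two contributions: the intrinsic half-width of
#' the cell nearest the criterion (sigma * sqrt(2 ln 2), which scales
#' with the timed duration) and the epsilon-determined half-width of the
#' learned weight profile (constant). Scalar timing is observed only
#' when the cell width dominates; when the tuning curves are very narrow
#' the field width is pinned at epsilon regardless of duration. The tie
#' is classified `learning_limited` (scalar requires strict dominance).
#'
#' @param sigma_at_criterion width of the cell nearest the criterion, s.
#' @param epsilon learning-rule offset, s.
#' @return `"scalar"` or `"learning_limited"`.
#' @examples
#' scalar_regime(2, 0.5)
#' scalar_regime(0.1, 0.5)
#' @export
scalar_regime <- function(sigma_at_criterion, epsilon) {
  if (width_cell(sigma_at_criterion) > width_learn(epsilon)) "scalar"
  else "learning_limited"
}

#' Timing error bound of a population
#'
#' min_k |T - t_k|: the model cannot time more accurately than the
#' temporal distance to the closest available cell, whatever the
#' learning rule does. A sparse map therefore biases the field peak
#' toward the nearest cell.
#'
#' @param pop a non-empty [time_cell_population].
#' @param criterion criterion time in seconds.
#' @return The minimum distance in seconds.
#' @examples
#' timing_error(make_fixture_population("sparse_T10"), 10)
#' @export
timing_error <- function(pop, criterion) {
  stopifnot(inherits(pop, "time_cell_population"))
  if (nrow(pop) == 0L)
    stop("cannot compute the timing error of an empty population", call. = FALSE)
  min(abs(criterion - pop$peak_time))
}

#' Scalar-property report across criterion times
#'
#' Runs the full pipeline (uniform population, training, average field,
#' width measurement) once per criterion with the same relative
#' configuration, and reports each field's peak, half-width and
#' width/criterion ratio. Under the scalar property the ratio is the
#' same for every criterion; with a fixed epsilon it is constant only up
#' to the epsilon-induced deviation, and exactly constant when epsilon
#' is scaled with the criterion (`scale_epsilon = TRUE`).
#'
#' @param criteria numeric vector of >= 2 criterion times, seconds.
#' @param n_cells,boundary_factor,cv population parameters per
#'   [make_uniform_population].
#' @param epsilon learning offset for the first criterion, seconds; under
#'   `scale_epsilon` the value used for criterion T is
#'   `epsilon * T / criteria[1]`.
#' @param n_trials trials per criterion.
#' @param scale_epsilon logical; default FALSE (fixed epsilon).
#' @param grid_step_divisor the grid step is `criterion / grid_step_divisor`.
#' @return A data frame of class `scalar_report` with columns
#'   `criterion`, `epsilon`, `peak_time`, `half_width_mean`,
#'   `width_over_criterion`, plus attribute `width_ratios` (matrix of
#'   pairwise half-width ratios).
#' @examples
#' scalar_report(c(10, 30), n_cells = 100)
#' @export
scalar_report <- function(criteria, n_cells = 100, boundary_factor = 3,
                          cv = 0.2, epsilon = 0.5, n_trials = 1L,
                          scale_epsilon = FALSE, grid_step_divisor = 1000) {
  if (length(criteria) < 2L)
    stop("need at least two criterion times to compare widths", call. = FALSE)
  rows <- lapply(criteria, function(criterion) {
    eps <- if (scale_epsilon) epsilon * criterion / criteria[1L] else epsilon
    pop <- make_uniform_population(criterion, n_cells, boundary_factor, cv)
    cfg <- learning_config(criterion, epsilon = eps, n_trials = n_trials)
    trained <- train(pop, cfg)$population
    grid <- time_grid(0, boundary_factor * criterion,
                      criterion / grid_step_divisor)
    rep <- measure_width(average_time_field(trained, grid))
    data.frame(criterion = criterion, epsilon = eps,
               peak_time = rep$peak_time,
               half_width_mean = rep$half_width_mean,
               width_over_criterion = rep$half_width_mean / criterion)
  })
  out <- do.call(rbind, rows)
  ratios <- outer(out$half_width_mean, out$half_width_mean, "/")
  dimnames(ratios) <- list(paste0("T", out$criterion), paste0("T", out$criterion))
  attr(out, "width_ratios") <- ratios
  class(out) <- c("scalar_report", "data.frame")
  out
}

#' Serialize field-analysis results
#'
#' `write_time_field` writes CSV `time_s,amplitude`; `write_width_report`
#' and `write_scalar_report` write JSON with the field names used by the
#' report objects.
#'
#' @param field a `time_field`; `report` a `width_report` or
#'   `scalar_report`.
#' @param path file path.
#' @return `path`, invisibly.
#' @name field_io
NULL

#' @rdname field_io
#' @export
write_time_field <- function(field, path) {
  stopifnot(inherits(field, "time_field"))
  utils::write.csv(data.frame(time_s = field$grid$times,
                              amplitude = field$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname field_io
#' @param report a `width_report` or `scalar_report`.
#' @export
write_width_report <- function(report, path) {
  stopifnot(inherits(report, "width_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname field_io
#' @export
write_scalar_report <- function(report, path) {
  stopifnot(inherits(report, "scalar_report"))
  obj <- list(rows = as.data.frame(report),
              width_ratios = attr(report, "width_ratios"))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}
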