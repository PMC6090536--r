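#' Construct a population of Gaussian time cells
#'
#' A time-cell population is the model's long-term memory: a spatially
#' ordered (topological) register in which cell index runs from ventral
#' (shortest peak time) to dorsal (longest peak time). Each cell is a
#' Gaussian temporal receptive field with peak time \eqn{t_n}, width
#' \eqn{\sigma_n} and amplitude (weight) \eqn{A_n}.
#'
#' @param peak_time numeric vector of peak times in seconds, all > 0.
#' @param sigma numeric vector of Gaussian widths in seconds, all > 0.
#'   Defaults to `cv * peak_time` (the scalar-width construction: field
#'   width proportional to peak time, as observed in hippocampal
#'   recordings).
#' @param weight numeric vector of non-negative amplitudes; default 1 for
#'   every cell (uniform initial weights before learning).
#' @param cv dimensionless width/peak-time proportionality constant used
#'   when `sigma` is not given. Default 0.2.
#' @param boundary upper end of the covered peak times in seconds;
#'   defaults to `max(peak_time)`.
#'
#' @return An object of class `time_cell_population`: a data frame with
#'   columns `peak_time`, `sigma`, `weight`, rows sorted ascending by
#'   `peak_time` (ventral to dorsal), and attributes `cv` and `boundary`.
#' @examples
#' pop <- time_cell_population(c(4, 6, 8, 12, 14))
#' pop
#' @export
time_cell_population <- function(peak_time, sigma = cv * peak_time,
                                 weight = rep(1, length(peak_time)),
                                 cv = 0.2, boundary = max(peak_time)) {
  peak_time <- as.numeric(peak_time)
  sigma <- as.numeric(sigma)
  weight <- as.numeric(weight)
  if (length(peak_time) == 0L)
    stop("population must contain at least one time cell", call. = FALSE)
  if (length(sigma) != length(peak_time) || length(weight) != length(peak_time))
    stop("'peak_time', 'sigma' and 'weight' must have equal length", call. = FALSE)
  if (any(!is.finite(peak_time)) || any(peak_time <= 0))
    stop("all peak times must be finite and > 0", call. = FALSE)
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("all sigma values must be finite and > 0", call. = FALSE)
  if (any(!is.finite(weight)) || any(weight < 0))
    stop("all weights must be finite and >= 0", call. = FALSE)
  if (anyDuplicated(peak_time))
    stop("peak times must be distinct (strict ventral-to-dorsal order)", call. = FALSE)
  if (!is.finite(boundary) || boundary < max(peak_time))
    stop("'boundary' must be >= the largest peak time", call. = FALSE)

  ord <- order(peak_time)
  pop <- data.frame(peak_time = peak_time[ord],
                    sigma = sigma[ord],
                    weight = weight[ord])
  attr(pop, "cv") <- cv
  attr(pop, "boundary") <- as.numeric(boundary)
  class(pop) <- c("time_cell_population", "data.frame")
  pop
}

#' Uniformly spaced time-cell population covering a criterion time
#'
#' Places `n_cells` cells with peak times evenly spaced over
#' `(0, boundary_factor * criterion]` at
#' `t_i = i * boundary / n_cells`, i = 1..n_cells (no cell sits at t = 0,
#' where the proportional width `cv * t` would degenerate). The default
#' temporal boundary is three times the criterion: the population covers
#' the to-be-timed duration with margin, analogous to place cells tied to
#' environmental boundaries. All widths are `cv * peak_time` and all
#' initial weights are 1.
#'
#' @param criterion to-be-learned criterion time T, seconds, > 0.
#' @param n_cells number of time cells, >= 2.
#' @param boundary_factor ratio of the temporal boundary to the criterion,
#'   > 1 so the criterion is covered; default 3.
#' @param cv width/peak-time proportionality constant, > 0; default 0.2.
#' @return A [time_cell_population] sorted ventral to dorsal.
#' @examples
#' make_uniform_population(criterion = 10, n_cells = 30)
#' @export
make_uniform_population <- function(criterion, n_cells, boundary_factor = 3,
                                    cv = 0.2) {
  if (!is.numeric(criterion) || length(criterion) != 1L || !is.finite(criterion) ||
      criterion <= 0)
    stop("'criterion' must be a single positive number", call. = FALSE)
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 2 ||
      n_cells != round(n_cells))
    stop("'n_cells' must be an integer >= 2", call. = FALSE)
  if (!is.numeric(boundary_factor) || length(boundary_factor) != 1L ||
      !is.finite(boundary_factor) || boundary_factor <= 1)
    stop("'boundary_factor' must be > 1", call. = FALSE)
  if (!is.numeric(cv) || length(cv) != 1L || !is.finite(cv) || cv <= 0)
    stop("'cv' must be a single positive number", call. = FALSE)

  boundary <- boundary_factor * criterion
  peaks <- seq_len(n_cells) * (boundary / n_cells)
  time_cell_population(peaks, cv = cv, boundary = boundary)
}

#' Packaged example populations
#'
#' Three small configurations used throughout the documentation and tests:
#' `fig2_T10` (five representative cells at 4, 6, 8, 12, 14 s, for a
#' criterion of 10 s), `fig2_T30` (the same layout scaled threefold:
#' 12, 18, 24, 36, 42 s, criterion 30 s) and `sparse_T10` (a sparse,
#' asymmetric population at 6, 8, 12, 20, 30 s whose closest cell to the
#' 10 s criterion is 2 s away). All start with unit weights and
#' `sigma = cv * peak_time`.
#'
#' @param name one of `"fig2_T10"`, `"fig2_T30"`, `"sparse_T10"`.
#' @param cv width/peak-time constant; default 0.2.
#' @return A [time_cell_population].
#' @examples
#' make_fixture_population("sparse_T10")
#' @export
make_fixture_population <- function(name = c("fig2_T10", "fig2_T30", "sparse_T10"),
                                    cv = 0.2) {
  name <- match.arg(name)
  peaks <- switch(name,
    fig2_T10   = c(4, 6, 8, 12, 14),
    fig2_T30   = c(12, 18, 24, 36, 42),
    sparse_T10 = c(6, 8, 12, 20, 30)
  )
  boundary <- switch(name, fig2_T10 = 30, fig2_T30 = 90, sparse_T10 = 30)
  time_cell_population(peaks, cv = cv, boundary = boundary)
}

#' Gaussian firing rate of time cells
#'
#' Evaluates \eqn{a_n(t) = A_n \exp(-(t - t_n)^2 / (2 \sigma_n^2))} for
#' every cell of a population at the times `t`. The "rate" is the abstract
#' tuning-curve amplitude of the model, not a spiking rate.
#'
#' @param pop a [time_cell_population].
#' @param t numeric vector of times in seconds (any finite value; the
#'   Gaussian is defined everywhere).
#' @return A numeric matrix with `length(t)` rows and one column per cell,
#'   ordered ventral to dorsal.
#' @examples
#' pop <- time_cell_population(10, sigma = 2)
#' firing_rate(pop, c(8, 10, 12))
#' @export
firing_rate <- function(pop, t) {
  stopifnot(inherits(pop, "time_cell_population"))
  if (any(!is.finite(t))) stop("'t' must be finite", call. = FALSE)
  out <- outer(t, seq_len(nrow(pop)), function(ti, k) {
    pop$weight[k] * exp(-(ti - pop$peak_time[k])^2 / (2 * pop$sigma[k]^2))
  })
  colnames(out) <- rownames(pop)
  out
}

#' Lesion one end of the topological map
#'
#' Removes `floor(fraction * N)` cells from the chosen end of the ordered
#' map: a ventral lesion ablates the cells with the shortest peak times, a
#' dorsal lesion those with the longest. Surviving cells keep their weights.
#' Mirrors the experimental observation that dorsal hippocampal lesions
#' shift behavioral peak times leftward (toward shorter durations) and
#' ventral lesions rightward.
#'
#' @param pop a [time_cell_population].
#' @param side `"ventral"` (remove shortest peaks) or `"dorsal"` (longest).
#' @param fraction fraction of cells to remove, in \[0, 1\].
#' @return A new [time_cell_population]; the input is unchanged. A full
#'   ablation (`fraction = 1`, or small populations where
#'   `floor(fraction * N) == N`) returns an object of class
#'   `time_cell_population` with zero rows, which downstream field
#'   operations reject.
#' @examples
#' pop <- make_uniform_population(10, 10)
#' lesion(pop, "dorsal", 0.3)
#' @export
lesion <- function(pop, side = c("ventral", "dorsal"), fraction) {
  stopifnot(inherits(pop, "time_cell_population"))
  side <- match.arg(side)
  if (!is.numeric(fraction) || length(fraction) != 1L || !is.finite(fraction) ||
      fraction < 0 || fraction > 1)
    stop("'fraction' must be a single number in [0, 1]", call. = FALSE)
  n <- nrow(pop)
  n_remove <- floor(fraction * n)
  keep <- if (n_remove == 0L) {
    seq_len(n)
  } else if (side == "ventral") {
    seq.int(n_remove + 1L, length.out = n - n_remove)
  } else {
    seq_len(n - n_remove)
  }
  out <- pop[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cv") <- attr(pop, "cv")
  attr(out, "boundary") <- attr(pop, "boundary")
  class(out) <- class(pop)
  out
}

#' @export
print.time_cell_population <- function(x, ...) {
  cat(sprintf("Time-cell population: %d cells, boundary %.3g s, cv %.3g\n",
              nrow(x), attr(x, "boundary"), attr(x, "cv")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Normalized weight view of a population
#'
#' Returns weights divided by their sum. The learning rule itself never
#' normalizes; this accessor exists for presentation and comparison only.
#'
#' @param pop a [time_cell_population] with at least one positive weight.
#' @return Numeric vector summing to 1.
#' @export
normalized_weights <- function(pop) {
  stopifnot(inherits(pop, "time_cell_population"))
  s <- sum(pop$weight)
  if (s <= 0) stop("all weights are zero; cannot normalize", call. = FALSE)
  pop$weight / s
}

#' Write / read a population as CSV
#'
#' The on-disk dialect has header `cell_index,peak_time_s,sigma_s,weight`
#' with `cell_index` ascending = ventral to dorsal. `cv` and `boundary`
#' are stored as `#` comment lines so the round trip is lossless.
#'
#' @param pop a [time_cell_population].
#' @param path file path.
#' @return `write_population` returns `path` invisibly; `read_population`
#'   returns the reconstructed [time_cell_population].
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "time_cell_population"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cv=%.17g", attr(pop, "cv")), con)
  writeLines(sprintf("# boundary=%.17g", attr(pop, "boundary")), con)
  writeLines("cell_index,peak_time_s,sigma_s,weight", con)
  if (nrow(pop) > 0L) {
    lines <- sprintf("%d,%.17g,%.17g,%.17g",
                     seq_len(nrow(pop)), pop$peak_time, pop$sigma, pop$weight)
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  header <- readLines(path, n = 2L)
  meta <- function(key, line) as.numeric(sub(sprintf("^# %s=", key), "", line))
  cv <- meta("cv", header[1L])
  boundary <- meta("boundary", header[2L])
  df <- utils::read.csv(path, comment.char = "#")
  time_cell_population(df$peak_time_s, sigma = df$sigma_s, weight = df$weight,
                       cv = cv, boundary = boundary)
}
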