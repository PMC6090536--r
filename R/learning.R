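#' Learning configuration
#'
#' Bundles the parameters of the error-driven multiplicative learning
#' rule: the to-be-learned criterion time T, the regularizing offset
#' epsilon of the error signal, the number of trials, and the common
#' initial weight.
#'
#' epsilon plays two roles: it prevents division by zero when a cell
#' peaks exactly at the criterion, and it sets the half-width of the
#' learned weight profile (see [width_learn]). The default 0.5 s
#' reproduces the reference five-cell weight trajectories exactly
#' (1/2.5 = 0.4, 1/4.5 = 0.22, 1/6.5 = 0.15 after one trial).
#'
#' @param criterion criterion time T in seconds, > 0.
#' @param epsilon regularizing offset in seconds, > 0; default 0.5.
#' @param n_trials number of learning trials, integer >= 1; default 1.
#' @param initial_weight common starting amplitude A0, > 0; default 1.
#' @return An object of class `learning_config`.
#' @examples
#' learning_config(criterion = 10, n_trials = 2)
#' @export
learning_config <- function(criterion, epsilon = 0.5, n_trials = 1L,
                            initial_weight = 1) {
  if (!is.numeric(criterion) || length(criterion) != 1L || !is.finite(criterion) ||
      criterion <= 0)
    stop("'criterion' must be a single positive number", call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0)
    stop("'epsilon' must be > 0 (guards the learning-rule singularity)",
         call. = FALSE)
  if (!is.numeric(n_trials) || length(n_trials) != 1L || !is.finite(n_trials) ||
      n_trials < 1 || n_trials != round(n_trials))
    stop("'n_trials' must be an integer >= 1", call. = FALSE)
  if (!is.numeric(initial_weight) || length(initial_weight) != 1L ||
      !is.finite(initial_weight) || initial_weight <= 0)
    stop("'initial_weight' must be > 0", call. = FALSE)
  structure(list(criterion = as.numeric(criterion),
                 epsilon = as.numeric(epsilon),
                 n_trials = as.integer(n_trials),
                 initial_weight = as.numeric(initial_weight)),
            class = "learning_config")
}

#' @export
print.learning_config <- function(x, ...) {
  cat(sprintf("Learning config: T = %g s, epsilon = %g s, %d trial(s), A0 = %g\n",
              x$criterion, x$epsilon, x$n_trials, x$initial_weight))
  invisible(x)
}

#' Error signal of the learning rule
#'
#' err_k = |T - t_k| + epsilon: the temporal distance from a cell's peak
#' to the criterion, regularized by epsilon so the multiplicative update
#' never divides by zero. Strictly positive for epsilon > 0.
#'
#' @param criterion criterion time T, seconds.
#' @param peak_time cell peak time(s) t_k, seconds (vectorized).
#' @param epsilon regularizing offset, seconds, > 0.
#' @return Numeric vector of error signals, seconds.
#' @examples
#' error_signal(10, c(4, 6, 8, 12, 14), 0.5)
#' @export
error_signal <- function(criterion, peak_time, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0)
    stop("'epsilon' must be > 0 (guards the learning-rule singularity)",
         call. = FALSE)
  abs(criterion - peak_time) + epsilon
}

#' Apply one learning trial
#'
#' The multiplicative update A_k <- A_k / err_k, with
#' err_k = |T - t_k| + epsilon. Cells peaking far from the criterion are
#' depressed more strongly than cells peaking near it; peak times and
#' widths are untouched, so the topological order is preserved.
#'
#' @param pop a non-empty [time_cell_population].
#' @param cfg a [learning_config] (its `n_trials` is ignored here; one
#'   trial is applied).
#' @return A new [time_cell_population] with updated weights.
#' @examples
#' pop <- make_fixture_population("fig2_T10")
#' apply_trial(pop, learning_config(criterion = 10))
#' @export
apply_trial <- function(pop, cfg) {
  stopifnot(inherits(pop, "time_cell_population"), inherits(cfg, "learning_config"))
  if (nrow(pop) == 0L)
    stop("cannot train an empty population", call. = FALSE)
  err <- error_signal(cfg$criterion, pop$peak_time, cfg$epsilon)
  out <- pop
  out$weight <- pop$weight / err
  out
}

#' Train a population toward one criterion time
#'
#' Applies [apply_trial] `cfg$n_trials` times, starting from weights all
#' equal to `cfg$initial_weight`. Because the per-trial error signal does
#' not depend on the weights, n trials produce the power-law profile
#' A_k(n) = A0 / (|T - t_k| + epsilon)^n, which [closed_form_weights]
#' computes directly and which the test suite uses as an independent
#' oracle.
#'
#' @param pop a non-empty [time_cell_population]; its current weights are
#'   replaced by `cfg$initial_weight` before the first trial (set
#'   `reset_weights = FALSE` to continue from the weights in `pop`, as
#'   multi-criterion training does).
#' @param cfg a [learning_config].
#' @param reset_weights logical; default TRUE.
#' @return A list of class `training_result` with elements
#'   `population` (the trained [time_cell_population]) and `history`
#'   (data frame `trial, cell_index, peak_time, weight` holding the full
#'   weight trajectory, trial 0 = initial state).
#' @examples
#' pop <- make_fixture_population("fig2_T10")
#' fit <- train(pop, learning_config(criterion = 10, n_trials = 2))
#' fit$population
#' @export
train <- function(pop, cfg, reset_weights = TRUE) {
  stopifnot(inherits(pop, "time_cell_population"), inherits(cfg, "learning_config"))
  if (nrow(pop) == 0L)
    stop("cannot train an empty population", call. = FALSE)
  cur <- pop
  if (reset_weights) cur$weight <- rep(cfg$initial_weight, nrow(cur))
  n <- nrow(cur)
  history <- vector("list", cfg$n_trials + 1L)
  history[[1L]] <- data.frame(trial = 0L, cell_index = seq_len(n),
                              peak_time = cur$peak_time, weight = cur$weight)
  for (trial in seq_len(cfg$n_trials)) {
    cur <- apply_trial(cur, cfg)
    history[[trial + 1L]] <- data.frame(trial = trial, cell_index = seq_len(n),
                                        peak_time = cur$peak_time,
                                        weight = cur$weight)
  }
  structure(list(population = cur, history = do.call(rbind, history)),
            class = "training_result")
}

#' @export
print.training_result <- function(x, ...) {
  n_trials <- max(x$history$trial)
  cat(sprintf("Training result after %d trial(s):\n", n_trials))
  print(x$population, ...)
  invisible(x)
}

#' Closed-form weights after n trials
#'
#' The analytic consequence of iterating the multiplicative rule:
#' A_k(n) = A0 / (|T - t_k| + epsilon)^n. Serves as the independent
#' oracle for [train]; the two must agree to floating-point tolerance
#' for every configuration.
#'
#' @param peak_times numeric vector of cell peak times, seconds.
#' @param cfg a [learning_config].
#' @return Numeric vector of weights, one per peak time.
#' @examples
#' closed_form_weights(c(4, 6, 8, 12, 14), learning_config(10, n_trials = 2))
#' @export
closed_form_weights <- function(peak_times, cfg) {
  stopifnot(inherits(cfg, "learning_config"))
  cfg$initial_weight *
    error_signal(cfg$criterion, peak_times, cfg$epsilon)^(-cfg$n_trials)
}

#' Train toward several criterion times in sequence
#'
#' Runs [train] once per criterion, carrying the weights forward between
#' criteria (no reset and no decay). After training T1 then T2, a cell
#' peaking exactly at T1 has weight A0 / (epsilon^n (|T2 - T1| + epsilon)^n)
#' and a cell at T2 the same value by symmetry of the product, so the
#' cells at the memorized criteria end up holding the largest weights
#' without any counter mechanism distinguishing the two durations.
#'
#' @param pop a non-empty [time_cell_population].
#' @param criteria numeric vector of criterion times, seconds, each > 0.
#' @param trials_per_criterion integer >= 1; trials run for each criterion.
#' @param epsilon regularizing offset, seconds; default 0.5.
#' @param initial_weight starting amplitude before the first criterion.
#' @return A [time_cell_population] with the final weights.
#' @examples
#' pop <- time_cell_population(c(5, 10, 50, 100, 150))
#' train_multi(pop, criteria = c(10, 100), trials_per_criterion = 1)
#' @export
train_multi <- function(pop, criteria, trials_per_criterion = 1L,
                        epsilon = 0.5, initial_weight = 1) {
  stopifnot(inherits(pop, "time_cell_population"))
  if (length(criteria) < 1L)
    stop("at least one criterion time is required", call. = FALSE)
  cur <- pop
  cur$weight <- rep(initial_weight, nrow(cur))
  for (criterion in criteria) {
    cfg <- learning_config(criterion, epsilon = epsilon,
                           n_trials = trials_per_criterion,
                           initial_weight = initial_weight)
    cur <- train(cur, cfg, reset_weights = FALSE)$population
  }
  cur
}

#' Write a weight-history CSV
#'
#' Dialect: `trial,cell_index,peak_time_s,weight`. Weights are written in
#' full precision; round only at presentation time.
#'
#' @param result a `training_result` from [train].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_weight_history <- function(result, path) {
  stopifnot(inherits(result, "training_result"))
  h <- result$history
  df <- data.frame(trial = h$trial, cell_index = h$cell_index,
                   peak_time_s = h$peak_time, weight = h$weight)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
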