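# Shared shorthand for the suite.

# Peak location of the trained average field for a population.
trained_peak <- function(pop, criterion, epsilon = 0.5, n_trials = 1L,
                         grid = default_grid(criterion,
                                             attr(pop, "boundary"))) {
  trained <- train(pop, learning_config(criterion, epsilon, n_trials))$population
  measure_width(average_time_field(trained, grid))$peak_time
}

# Mean half-width of the trained field for one of the packaged fixtures.
fixture_half_width <- function(name, criterion, epsilon = 0.5, n_trials = 1L) {
  pop <- make_fixture_population(name)
  trained <- train(pop, learning_config(criterion, epsilon, n_trials))$population
  grid <- default_grid(criterion, attr(pop, "boundary"))
  measure_width(average_time_field(trained, grid))$half_width_mean
}
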