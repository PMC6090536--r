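test_that("time grids validate their geometry", {
  g <- time_grid(0, 30, 0.01)
  expect_equal(g$times[1], 0)
  expect_equal(length(g$times), 3001L)
  expect_error(time_grid(10, 10, 0.01), "start")
  expect_error(time_grid(0, 30, -1), "step")
  expect_error(time_grid(0, 30, 1), "coarse")   # fewer than 100 steps
})

test_that("the average field is the weighted Gaussian sum and linear in weights", {
  grid <- time_grid(0, 30, 0.01)
  one <- time_cell_population(10, sigma = 2, weight = 0.8)
  f <- average_time_field(one, grid)
  expect_equal(f$values, 0.8 * exp(-(grid$times - 10)^2 / 8))

  pop <- make_fixture_population("fig2_T10")
  f1 <- average_time_field(pop, grid)
  doubled <- pop; doubled$weight <- 2 * pop$weight
  f2 <- average_time_field(doubled, grid)
  expect_equal(f2$values, 2 * f1$values)
  expect_true(all(f1$values >= 0))
  expect_error(average_time_field(lesion(pop, "dorsal", 1), grid), "empty")
})

test_that("measured half-widths agree with the analytic single-cell value", {
  pop <- time_cell_population(10, sigma = 2)
  rep <- measure_width(average_time_field(pop, time_grid(0, 30, 0.005)))
  expect_equal(rep$peak_time, 10, tolerance = 0.005)
  expect_equal(rep$half_width_left, width_cell(2), tolerance = 0.01)
  expect_equal(rep$half_width_right, width_cell(2), tolerance = 0.01)
  expect_equal(width_cell(1), sqrt(2 * log(2)))
  expect_equal(width_cell(2), 2 * width_cell(1))
  expect_error(width_cell(0), "sigma")
})

test_that("a side that never falls to half maximum is reported NA, not invented", {
  # wide cell close to the grid edge: the left side never crosses half max
  pop <- time_cell_population(0.5, sigma = 5)
  rep <- measure_width(average_time_field(pop, time_grid(0, 30, 0.01)))
  expect_true(is.na(rep$half_width_left))
  expect_false(is.na(rep$half_width_right))
  expect_equal(rep$half_width_mean, rep$half_width_right)
  flat <- structure(list(grid = time_grid(0, 30, 0.01),
                         values = rep(1, 3001)), class = "time_field")
  expect_error(measure_width(flat), "degenerate")
})

test_that("trained fields peak at the criterion and are symmetric for symmetric maps", {
  # dense uniform coverage: peak within cell spacing / 2 + one grid step of T
  pop <- make_uniform_population(10, 60)            # spacing 0.5 s
  trained <- train(pop, learning_config(10))$population
  rep <- measure_width(average_time_field(trained, default_grid(10)))
  expect_lt(abs(rep$peak_time - 10), 0.5 / 2 + 0.01)
  # a population fully symmetric about T (peaks and widths) gives a
  # symmetric field; width-peak proportionality otherwise skews it right
  sym <- time_cell_population(10 + c(-4, -2, 0, 2, 4), sigma = rep(1.5, 5))
  strained <- train(sym, learning_config(10))$population
  srep <- measure_width(average_time_field(strained, time_grid(0, 20, 0.01)))
  expect_equal(srep$peak_time, 10, tolerance = 0.011)
  expect_equal(srep$half_width_left, srep$half_width_right, tolerance = 0.02)
})

test_that("the envelope narrows as trials accumulate", {
  widths10 <- vapply(1:5, function(n) fixture_half_width("fig2_T10", 10, n_trials = n),
                     numeric(1))
  widths30 <- vapply(1:5, function(n) fixture_half_width("fig2_T30", 30, n_trials = n),
                     numeric(1))
  expect_true(all(diff(widths10) < 0))
  expect_true(all(diff(widths30) < 0))
})

test_that("the learning-rule width is epsilon and the regime flips exactly at the tie", {
  expect_equal(width_learn(0.5), 0.5)
  expect_error(width_learn(0), "epsilon")
  # weight profile at distance epsilon is half its maximum
  eps <- 0.37
  expect_equal(1 / error_signal(10, 10 + eps, eps),
               0.5 / error_signal(10, 10, eps))
  expect_identical(scalar_regime(2, 0.5), "scalar")
  expect_identical(scalar_regime(0.1, 0.5), "learning_limited")
  # strict dominance required: the tie sits in the learning-limited class
  sigma_tie <- 0.5 / sqrt(2 * log(2))
  expect_identical(scalar_regime(sigma_tie, 0.5), "learning_limited")
  expect_identical(scalar_regime(sigma_tie * (1 + 1e-9), 0.5), "scalar")
})

test_that("timing error is the distance to the closest available cell", {
  expect_equal(timing_error(make_fixture_population("sparse_T10"), 10), 2)
  expect_equal(timing_error(time_cell_population(c(3, 10, 20)), 10), 0)
  # uniform spacing s pigeonholes the error at s/2
  pop <- make_uniform_population(10, 30)   # spacing 1 s
  for (Tq in c(2.2, 9.6, 14.49, 25.01))
    expect_lte(timing_error(pop, Tq), 0.5)
  expect_error(timing_error(lesion(pop, "dorsal", 1), 10), "empty")
})

test_that("sparse asymmetric maps bias the field peak toward the nearest cell", {
  sp <- train(make_fixture_population("sparse_T10"), learning_config(10))$population
  rep <- measure_width(average_time_field(sp, time_grid(0, 35, 0.01)))
  expect_lt(abs(rep$peak_time - 8), abs(rep$peak_time - 10))
})

test_that("the whole pipeline is scale covariant under k-fold time scaling", {
  base_pop <- make_uniform_population(10, 30)
  base_grid <- time_grid(0, 30, 0.01)
  base <- train(base_pop, learning_config(10, epsilon = 0.5, n_trials = 2))$population
  base_rep <- measure_width(average_time_field(base, base_grid))
  for (k in c(3, 11.5)) {
    pop_k <- make_uniform_population(10 * k, 30)
    grid_k <- time_grid(0, 30 * k, 0.01 * k)
    scaled <- train(pop_k, learning_config(10 * k, epsilon = 0.5 * k,
                                           n_trials = 2))$population
    rep_k <- measure_width(average_time_field(scaled, grid_k))
    expect_equal(rep_k$peak_time, k * base_rep$peak_time, tolerance = 1e-9)
    expect_equal(rep_k$half_width_mean, k * base_rep$half_width_mean,
                 tolerance = 1e-9)
  }
})

test_that("peak location is insensitive to the number of cells", {
  peaks <- vapply(c(10, 100, 1000), function(n) {
    trained_peak(make_uniform_population(10, n), criterion = 10)
  }, numeric(1))
  # coarsest population spaces its cells 3 s apart
  expect_lt(max(peaks) - min(peaks), 3)
  expect_true(all(abs(peaks - 10) < 3))
})

test_that("scalar report keeps width/criterion near-constant and exact under scaled epsilon", {
  rep <- scalar_report(c(10, 30), n_cells = 100)
  expect_named(rep, c("criterion", "epsilon", "peak_time", "half_width_mean",
                      "width_over_criterion"))
  ratios <- attr(rep, "width_ratios")
  expect_equal(ratios["T30", "T10"], 3, tolerance = 0.2)
  exact <- scalar_report(c(10, 30), n_cells = 100, scale_epsilon = TRUE)
  expect_equal(attr(exact, "width_ratios")["T30", "T10"], 3, tolerance = 1e-8)
  # identical criteria give a ratio of exactly 1
  same <- scalar_report(c(10, 10), n_cells = 50)
  expect_identical(attr(same, "width_ratios")[1, 2], 1)
  # monotone widths across a scale ladder
  ladder <- scalar_report(c(10, 20, 40), n_cells = 60)
  expect_true(all(diff(ladder$half_width_mean) > 0))
  expect_error(scalar_report(10), "at least two")
})
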