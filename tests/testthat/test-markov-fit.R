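test_that("transition matrix estimation matches hand-enumerated pair counts", {
  f <- markov_fit(series_of(c(1, 1, 0, 0, 1)))
  expect_equal(unname(coef(f)), c(0.5, 0.5))
  expect_equal(with(f$matrix, n_rr + n_ru + n_uu + n_ur), f$n_pairs)
  expect_equal(f$n_pairs, 4L)

  f2 <- markov_fit(series_of(c(1, 0, 1, 0, 1)))
  expect_equal(unname(coef(f2)), c(0, 0))

  f3 <- markov_fit(series_of(c(1, 1, 1, 1)))
  expect_equal(f3$matrix$a, 1)
  expect_true(is.na(f3$matrix$b))
  expect_true(is.na(f3$p_u_given_u))

  expect_error(markov_fit(series_of(c(1, NA, 0))), "no valid")
  expect_error(markov_fit(trial_series("m", list(1L, 0L))), "no valid")
})

test_that("missing trials and session boundaries break the pair chain", {
  # NA splits: only (1,1) and (0,0) survive
  f <- markov_fit(series_of(c(1, 1, NA, 0, 0)))
  expect_equal(f$n_pairs, 2L)
  expect_equal(unname(coef(f)), c(1, 1))

  s <- trial_series("m", list(c(1L, 1L), c(0L, 0L)))
  expect_equal(markov_fit(s)$n_pairs, 2L)                 # within sessions
  expect_equal(markov_fit(s, cross_session = TRUE)$n_pairs, 3L)
})

test_that("stationary response probability follows (1-b)/(2-a-b)", {
  expect_equal(stationary_response_probability(
    transition_matrix(0.44, 0.56)), 0.44)              # Bernoulli at ec
  expect_equal(stationary_response_probability(
    transition_matrix(0.3, 0.3)), 0.5)                 # symmetric chain
  expect_equal(stationary_response_probability(
    transition_matrix(0.8, 0.6)), 2 / 3, tolerance = 1e-12)
  expect_error(stationary_response_probability(transition_matrix(1, 1)),
               "absorbing")

  # long-run empirical mean of a simulated chain agrees within 3 SE
  s <- simulate_markov_series(0.8, 0.6, 1, 20000, seed = 9)
  p_hat <- mean(pooled_trials(s))
  # asymptotic variance of the mean of a 2-state chain:
  # p(1-p)/n * (1+lambda2)/(1-lambda2)
  se <- sqrt((2 / 3) * (1 / 3) / 20000 * (1 + 0.4) / (1 - 0.4))
  expect_close(p_hat, 2 / 3, 3 * se)
})

test_that("transition fraction is the empirical switch rate and matches counts", {
  expect_equal(transition_fraction(series_of(c(1, 0, 1, 0, 1))), 1)
  expect_equal(transition_fraction(series_of(rep(1, 6))), 0)
  expect_equal(transition_fraction(series_of(c(1, 1, 0, 0, 1))), 0.5)

  # identity: 1 - occupancy-weighted average of a and b
  f <- markov_fit(structured_cohort(seed = 2, n_animals = 1)$cohort$series[[1]])
  m <- f$matrix
  w_r <- (m$n_rr + m$n_ru) / f$n_pairs
  expect_equal(f$transition_fraction,
               1 - (w_r * m$a + (1 - w_r) * m$b), tolerance = 1e-12)
})

test_that("parameter recovery: estimates converge to the generating matrix", {
  for (truth in list(c(0.8, 0.6), c(0.55, 0.9))) {
    s <- simulate_markov_series(truth[1], truth[2], 1, 10000,
                                seed = 100 + round(10 * truth[1]))
    f <- markov_fit(s)
    expect_close(f$matrix$a, truth[1], 0.05)
    expect_close(f$matrix$b, truth[2], 0.05)
  }
})

test_that("dwell extraction separates complete and censored runs", {
  dw <- extract_dwell_times(series_of(c(1, 1, 0, 0, 0, 1)))
  expect_equal(dw$responsive, integer(0))
  expect_equal(dw$unresponsive, 3L)
  expect_equal(dw$censored_responsive, 2L)

  dw2 <- extract_dwell_times(series_of(rep(1, 8)))
  expect_equal(length(dw2$responsive) + length(dw2$unresponsive), 0L)
  expect_equal(dw2$censored_responsive + dw2$censored_unresponsive, 1L)

  expect_equal(extract_dwell_times(series_of(c(0, 1, 1, 0)))$responsive, 2L)

  # a run touching a missing trial is censored, not completed
  dw3 <- extract_dwell_times(series_of(c(0, 1, 1, NA, 0)))
  expect_equal(dw3$responsive, integer(0))
})

test_that("geometric dwell-rate MLE is n / sum(dwells)", {
  expect_equal(fit_dwell_rate(3), 1 / 3)
  expect_equal(fit_dwell_rate(c(2, 2, 4)), 0.375)
  expect_equal(fit_dwell_rate(rep(1, 5)), 1)
  expect_error(fit_dwell_rate(integer(0)), "no complete dwells")
})

test_that("autocorrelation matches analytic two-state chain values", {
  ac <- response_autocorrelation(series_of(rep(c(1, 0), 10)), max_lag = 2)
  expect_equal(ac$acf[1], -1)
  expect_equal(ac$acf[2], 1)
  expect_error(response_autocorrelation(series_of(rep(1, 10))), "variance")

  # lag-1 autocorrelation of a two-state chain equals lambda2 = a + b - 1
  s <- simulate_markov_series(0.9, 0.9, 1, 1e5, seed = 21)
  ac2 <- response_autocorrelation(s, max_lag = 3)
  expect_close(ac2$acf[1], 0.8, 0.02)
  expect_close(ac2$acf[2], 0.8^2, 0.03)

  # Bernoulli null: lag-1 inside the white-noise band in most replicates
  set.seed(31)
  inside <- replicate(200, {
    x <- rbinom(400, 1, 0.44)
    a <- response_autocorrelation(series_of(x), max_lag = 1)
    abs(a$acf[1]) < a$band[1]
  })
  expect_gte(mean(inside), 0.90)
})

test_that("spectral gap of the 2x2 chain is 2 - a - b", {
  sg <- spectral_gap(transition_matrix(0.44, 0.56))   # memoryless
  expect_equal(sg$lambda2, 0)
  expect_equal(sg$gap, 1)
  expect_equal(spectral_gap(transition_matrix(1, 1))$gap, 0)
  sg2 <- spectral_gap(transition_matrix(0.8, 0.6))
  expect_equal(unlist(sg2), c(trace = 1.4, lambda2 = 0.4, gap = 0.6))
  # agreement with a numeric eigendecomposition
  ev <- eigen(as.matrix(transition_matrix(0.8, 0.6)))$values
  expect_equal(sort(ev), sort(c(1, 0.4)), tolerance = 1e-12)
})

test_that("steady-state check detects trends and is calibrated when stationary", {
  trend <- cohort(lapply(1:3, function(k)
    series_of(c(0, 0, 0, 1, 1, 1, 1, 1), paste0("m", k))))
  ck <- steady_state_check(trend)
  expect_gt(ck$r, 0.8)

  # under stationarity, |r| exceeds the 5% critical value ~5% of the time
  set.seed(17)
  n_rep <- 400
  hits <- replicate(n_rep, {
    co <- cohort(lapply(1:8, function(k)
      series_of(rbinom(40, 1, 0.5), paste0("m", k))))
    steady_state_check(co)$p_value < 0.05
  })
  expect_close(mean(hits), 0.05, 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("markov_fit methods: predict, simulate, residuals are coherent", {
  s <- simulate_markov_series(0.8, 0.6, 2, 200, seed = 5)
  f <- markov_fit(s)
  # stationary start: prediction constant at the stationary probability
  p_stat <- stationary_response_probability(f)
  expect_equal(predict(f, c(1, 5, 20)), rep(p_stat, 3), tolerance = 1e-12)
  # from R, predictions decay geometrically toward stationary
  p_r <- predict(f, 1:30, from = "R")
  expect_true(all(diff(p_r) <= 1e-12))
  expect_close(p_r[30], p_stat, 0.01)

  sims <- simulate(f, nsim = 2, seed = 8)
  expect_length(sims, 2)
  expect_equal(n_trials(sims[[1]]), n_trials(s))

  r <- residuals(f)
  expect_length(r, f$n_pairs)
  expect_close(mean(r), 0, 0.1)
})

test_that("per-animal summary table carries all derived quantities", {
  co <- structured_cohort(seed = 19, n_animals = 5)$cohort
  tab <- markov_summary_table(co)
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$trace, tab$a + tab$b)
  expect_equal(tab$gap, 2 - tab$trace)
  expect_equal(tab$p_u_given_r, 1 - tab$a)
  path <- withr::local_tempfile(fileext = ".csv")
  markov_summary_table(co, path = path)
  expect_equal(nrow(utils::read.csv(path)), 5L)
})
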