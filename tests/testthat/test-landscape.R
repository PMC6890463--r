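test_that("energy and gradient follow the closed forms", {
  expect_equal(well_energy(c(-1, 1), 0.5), c(0.5, 0.5))
  expect_equal(well_energy(0, 0.5), 1)

  # symmetry of the form: E(x, i) = E(-x, 1 - i)
  xs <- seq(-2, 2, 0.25); is <- seq(0, 1, 0.1)
  for (i in is)
    expect_equal(well_energy(xs, i), well_energy(-xs, 1 - i),
                 tolerance = 1e-12)

  expect_equal(well_gradient(c(-1, 0, 1), 0.5), c(0, 0, 0))
  expect_equal(well_gradient(0, 0), 2)   # drug-free: awake well favored

  # finite-difference oracle over a grid
  h <- 1e-4
  for (i in c(0, 0.3, 0.5, 0.9)) {
    fd <- (well_energy(xs + h, i) - well_energy(xs - h, i)) / (2 * h)
    expect_true(all(abs(well_gradient(xs, i) - fd) < 1e-6))
  }
})

test_that("noiseless dynamics settle on the fixed points", {
  p0 <- landscape_params(i = 0.5, sigma = 0, x0 = 1, n_steps = 500,
                         burn_in = 0)
  expect_true(all(simulate_langevin(p0) == 1))

  p1 <- landscape_params(i = 0.5, sigma = 0, x0 = 0.1, n_steps = 2000,
                         burn_in = 0)
  traj <- simulate_langevin(p1)
  expect_true(all(diff(traj) >= -1e-12))       # monotone climb out
  expect_close(traj[length(traj)], 1, 1e-6)
})

test_that("sigma = 0.4 gives a bimodal marginal with modes near the wells", {
  p <- landscape_params(i = 0.5, sigma = 0.4, n_steps = 2e5,
                        burn_in = 1e4, seed = 61)
  traj <- simulate_langevin(p)
  x <- traj[-(1:p$burn_in)]
  hist <- graphics::hist(x, breaks = 60, plot = FALSE)
  neg <- hist$mids < 0
  mode_neg <- hist$mids[neg][which.max(hist$counts[neg])]
  mode_pos <- hist$mids[!neg][which.max(hist$counts[!neg])]
  expect_close(mode_neg, -1, 0.3)
  expect_close(mode_pos, 1, 0.3)
  # both wells carry substantial mass at equal depth
  expect_gt(mean(x > 0), 0.2)
  expect_gt(mean(x < 0), 0.2)
})

test_that("binarize/decimate maps awake to responsive with the <= rule", {
  s <- binarize_decimate(rep(2, 500), decimation = 1)
  expect_true(all(pooled_trials(s) == 0L))       # anesthetized side
  # the boundary sample x = threshold counts as responsive
  expect_equal(pooled_trials(binarize_decimate(c(0, 0.1, -0.1),
                                               decimation = 1)),
               c(1L, 0L, 1L))
  # decimation and burn-in arithmetic
  s2 <- binarize_decimate(rnorm(1e4), decimation = 100, burn_in = 1000)
  expect_equal(n_trials(s2), 90L)
})

test_that("trajectory overflow is caught with actionable advice", {
  p <- landscape_params(i = 0.5, sigma = 0, x0 = 50, dt = 1,
                        n_steps = 10, burn_in = 0, drift_cap = Inf)
  expect_error(simulate_langevin(p), "smaller dt")
  # with the default tamed drift the same start relaxes into a well
  p2 <- landscape_params(i = 0.5, sigma = 0, x0 = 50, dt = 1,
                         n_steps = 200, burn_in = 0)
  traj <- simulate_langevin(p2)
  expect_lt(abs(traj[200]), 1.5)
})

test_that("noise level moves the chain between periphery and center", {
  base <- landscape_params(n_steps = 1e5, burn_in = 5e3, seed = 62)
  sw <- landscape_sweep(0.5, c(0.15, 5), base)
  # noise-dominated limit: (a, b) within 0.1 of (0.5, 0.5)
  hi <- sw[sw$sigma == 5, ]
  expect_close(hi$a, 0.5, 0.1)
  expect_close(hi$b, 0.5, 0.1)
  # rare-switching limit: trace near 2
  lo <- sw[sw$sigma == 0.15, ]
  expect_gt(lo$a + lo$b, 1.8)

  # strict monotonicity of switching in sigma, probed below the
  # saturation imposed by sparse sampling: at decimation 100 the
  # sample spacing exceeds the mixing time for sigma >~ 0.8 and the
  # transition fraction flattens at the memoryless 0.5, so the ladder
  # is checked at a 10-fold decimation
  base10 <- landscape_params(n_steps = 1e5, burn_in = 5e3,
                             decimation = 10L, seed = 62)
  sw10 <- landscape_sweep(0.5, c(0.15, 0.25, 0.4, 0.8), base10)
  expect_true(all(diff(sw10$transition_fraction) > 0))
  # mixing speeds up: lambda2 = a + b - 1 decreases with sigma
  expect_true(all(diff(sw10$a + sw10$b - 1) < 0))
})

test_that("drug effect at fixed noise traces the anti-diagonal", {
  base <- landscape_params(sigma = 0.4, n_steps = 1e5, burn_in = 5e3,
                           seed = 63)
  sw <- landscape_sweep(seq(0.3, 0.7, by = 0.05), 0.4, base)
  expect_true(all(!is.na(sw$a) & !is.na(sw$b)))
  expect_lt(cor(sw$a, sw$b), -0.9)
  # responsive fraction falls as the drug effect deepens the U well
  expect_lt(cor(sw$i, sw$responsive_fraction), -0.9)
})

test_that("statistics respect the i <-> 1 - i label-exchange symmetry", {
  base <- landscape_params(sigma = 0.4, n_steps = 1e5, burn_in = 5e3)
  p_lo <- base; p_lo$i <- 0.35; p_lo$seed <- 64
  p_hi <- base; p_hi$i <- 0.65; p_hi$seed <- 65
  f_lo <- markov_fit(simulate_landscape_series(p_lo))
  f_hi <- markov_fit(simulate_landscape_series(p_hi))
  # exchanging responsive/unresponsive labels swaps a and b
  expect_close(f_lo$matrix$a, f_hi$matrix$b, 0.1)
  expect_close(f_lo$matrix$b, f_hi$matrix$a, 0.1)
  # and at i = 0.5 the stationary responsive fraction is 1/2
  p_mid <- base; p_mid$i <- 0.5; p_mid$seed <- 66; p_mid$n_steps <- 4e5
  s_mid <- simulate_landscape_series(p_mid)
  x <- pooled_trials(s_mid)
  f_mid <- markov_fit(s_mid)
  lam <- f_mid$matrix$a + f_mid$matrix$b - 1
  se <- sqrt(0.25 / length(x) * (1 + lam) / (1 - lam))
  expect_close(mean(x), 0.5, 3 * se)
})
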