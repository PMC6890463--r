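test_that("density estimates integrate to one and respect the grid", {
  trapz <- function(g, y) sum(diff(g) * (y[-1] + y[-length(y)]) / 2)
  set.seed(41)
  for (fam in c("kde", "normal", "beta")) {
    f <- response_probability_density(rbeta(200, 4, 6), family = fam)
    expect_close(trapz(f$grid, f$density), 1, 1e-6)
    expect_true(all(f$density >= 0))
    expect_length(f$grid, 1001L)
  }
  expect_error(response_probability_density(c(0.2, 1.3)), "\\[0, 1\\]")
})

test_that("bootstrap distribution: defaults, degenerate and binomial-width cases", {
  # defaults follow the decoding procedure: 1000 resamples of 20 trials
  expect_equal(formals(bootstrap_response_distribution)$n_boot, 1000L)
  expect_equal(formals(bootstrap_response_distribution)$boot_size, 20L)

  ones <- series_of(rep(1, 160))
  f <- bootstrap_response_distribution(ones, 200, 20, seed = 1)
  # point mass: all mass within one grid step of 1.0
  step <- f$grid[2] - f$grid[1]
  mass_near_1 <- sum(f$density[f$grid > 1 - 5 * step]) /
    sum(f$density)
  expect_gte(mass_near_1, 0.99)

  # p = 0.5, 160 trials: SD of 20-trial bootstrap means ~ sqrt(0.25/20)
  half <- series_of(rep(c(1, 0), 80))
  g <- bootstrap_response_distribution(half, 2000, 20, seed = 2)
  expect_close(sd(attr(g, "boot_means")), sqrt(0.25 / 20), 0.015)

  expect_error(bootstrap_response_distribution(series_of(c(1, 0, 1)),
                                               100, 20),
               "at least boot_size")
})

test_that("overlap coefficient: identity, disjoint supports, symmetry, bounds", {
  set.seed(43)
  f <- response_probability_density(rbeta(500, 8, 4))
  g <- response_probability_density(rbeta(500, 4, 8))
  expect_equal(overlap_coefficient(f, f), 1, tolerance = 1e-6)
  o <- overlap_coefficient(f, g)
  expect_equal(o, overlap_coefficient(g, f))
  expect_true(o > 0 && o < 1)

  lo <- response_probability_density(runif(500, 0.02, 0.10))
  hi <- response_probability_density(runif(500, 0.90, 0.98))
  expect_lt(overlap_coefficient(lo, hi), 1e-3)

  h <- response_probability_density(rbeta(100, 2, 2), grid_n = 101)
  expect_error(overlap_coefficient(f, h), "grid")
})

test_that("overlap decreases as generating response probabilities separate", {
  set.seed(44)
  base <- series_of(rbinom(160, 1, 0.5), "ref")
  f0 <- bootstrap_response_distribution(base, 500, 20, seed = 3)
  seps <- c(0.55, 0.7, 0.85, 0.98)
  ovs <- vapply(seps, function(p) {
    s <- series_of(rbinom(160, 1, p), "cmp")
    overlap_coefficient(
      f0, bootstrap_response_distribution(s, 500, 20, seed = 4))
  }, numeric(1))
  expect_true(all(diff(ovs) < 0))
})

test_that("Bayes posterior follows the pointwise rule and sums to one", {
  set.seed(45)
  f1 <- response_probability_density(rbeta(300, 6, 4))
  f2 <- response_probability_density(rbeta(300, 4, 6))

  # identical likelihoods: posterior equals the prior everywhere defined
  same <- bayes_posterior(f1, f1, priors = c(0.3, 0.7))
  expect_true(all(abs(same$posterior[!is.na(same$posterior)] - 0.3) < 1e-9))

  post <- bayes_posterior(f1, f2)
  comp <- bayes_posterior(f2, f1)
  ok <- !is.na(post$posterior) & !is.na(comp$posterior)
  expect_true(all(abs(post$posterior[ok] + comp$posterior[ok] - 1) < 1e-9))

  # direct substitution: f1 = 2, f2 = 1 with flat priors -> 2/3
  mk <- function(d) structure(list(grid = f1$grid, density = d,
                                   bandwidth = NA, n_source = 1),
                              class = "density_estimate")
  flat2 <- mk(rep(2, length(f1$grid)))
  flat1 <- mk(rep(1, length(f1$grid)))
  expect_equal(unique(bayes_posterior(flat2, flat1)$posterior), 2 / 3)
  # one-sided support: posterior 1 where the alternative has no mass
  zero <- mk(rep(0, length(f1$grid)))
  p1 <- bayes_posterior(flat1, zero)
  expect_true(all(p1$posterior[!is.na(p1$posterior)] == 1))
  # both likelihoods underflowing: undefined, not 0/0
  expect_true(all(is.na(bayes_posterior(zero, zero)$posterior)))

  expect_error(bayes_posterior(f1, f2, priors = c(0, 0)), "not both zero")
})

test_that("per-animal overlap summary: identical and well-separated designs", {
  mk_cohort <- function(ps, label) cohort(
    lapply(seq_along(ps), function(k)
      series_of(rbinom(160, 1, ps[k]), sprintf("m%02d", k))),
    "isoflurane", 0.5, "% atm", label)

  set.seed(46)
  ps <- runif(6, 0.4, 0.6)
  c1 <- mk_cohort(ps, "first")
  # same animals, same behavior: overlaps near 1
  ov_same <- per_animal_overlap_summary(c1, c1, n_boot = 300, seed = 5)
  # two independent bootstrap KDEs of the same trials: overlap near 1,
  # short of it only by resampling noise in the density estimates
  expect_gte(min(ov_same$table$overlap), 0.85)
  expect_gte(ov_same$median, 0.90)

  # well-separated sensitivities: median overlap < 0.05
  lo <- mk_cohort(rep(0.05, 6), "low")
  hi <- mk_cohort(rep(0.95, 6), "high")
  ov_sep <- per_animal_overlap_summary(lo, hi, n_boot = 300, seed = 6)
  expect_lt(ov_sep$median, 0.05)
  expect_equal(ov_sep$iqr[["lower"]] <= ov_sep$median, TRUE)

  c2 <- mk_cohort(ps, "second")
  names(c2$series)[1] <- c2$series[[1]]$animal_id <- "other"
  expect_error(per_animal_overlap_summary(c1, c2), "same animals")
})

test_that("population response density summarises per-animal probabilities", {
  fix <- structured_cohort(seed = 47, n_animals = 10)
  f <- population_response_density(fix$cohort)
  expect_s3_class(f, "density_estimate")
  expect_equal(f$n_source, 10L)
})
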