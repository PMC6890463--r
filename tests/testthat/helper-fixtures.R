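# Shared fixtures, all generated in code.

series_of <- function(x, id = "m1", species = "mouse") {
  trial_series(id, list(as.integer(x)), species = species)
}

# A small structured mouse-like cohort with known generating matrices.
structured_cohort <- function(seed = 42, n_animals = 20L, ...) {
  sp <- cohort_spec(n_animals = n_animals, seed = seed, ...)
  mats <- suppressWarnings(sample_individual_matrices(sp))
  list(spec = sp, matrices = mats, cohort = generate_cohort(mats, sp))
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("%.6g within %.3g of %.6g",
                              object, tol, expected))
}
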