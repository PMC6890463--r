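#' Specification of a Bernoulli null simulation
#'
#' The memoryless null: every trial is responsive with a fixed
#' probability \code{ec} (the population effective concentration,
#' i.e. the overall response probability), independent of state.
#' Its transition matrix has a = ec and b = 1 - ec, so the trace is 1
#' and the second eigenvalue 0. The default design mirrors the mouse
#' experiments: 80 simulated 40-trial exposures grouped 4 per animal
#' into 20 simulated animals of 160 trials.
#'
#' @param ec Per-trial response probability in [0, 1].
#' @param n_experiments Number of simulated experiments (sessions).
#' @param n_trials_per_experiment Trials per experiment.
#' @param grouping Experiments per simulated animal; must divide
#'   \code{n_experiments}.
#' @param seed Optional integer seed.
#' @return An object of class \code{"bernoulli_spec"}.
#' @export
bernoulli_spec <- function(ec, n_experiments = 80L,
                           n_trials_per_experiment = 40L,
                           grouping = 4L, seed = NULL) {
  stopifnot(is.numeric(ec), length(ec) == 1L, ec >= 0, ec <= 1,
            n_experiments >= 1L, n_trials_per_experiment >= 1L,
            grouping >= 1L)
  if (n_experiments %% grouping != 0L)
    stop("'grouping' must divide 'n_experiments'")
  structure(list(ec = ec, n_experiments = as.integer(n_experiments),
                 n_trials_per_experiment = as.integer(n_trials_per_experiment),
                 grouping = as.integer(grouping), seed = seed),
            class = "bernoulli_spec")
}

#' Simulate a Bernoulli-process cohort
#'
#' Each trial is independently responsive with probability
#' \code{spec$ec}; because the process is memoryless, randomizing the
#' initial state is equivalent to drawing it from the same Bernoulli
#' law, which is what happens for every trial. Experiments are grouped
#' into simulated animals (sessions of one animal).
#'
#' @param spec A \code{\link{bernoulli_spec}}.
#' @param species Species label for the simulated series.
#' @return A \code{\link{cohort}} of
#'   \code{n_experiments / grouping} animals.
#' @examples
#' co <- simulate_bernoulli(bernoulli_spec(0.44, seed = 1))
#' length(co$series)  # 20
#' @export
simulate_bernoulli <- function(spec, species = "mouse") {
  stopifnot(inherits(spec, "bernoulli_spec"))
  n_animals <- spec$n_experiments %/% spec$grouping
  with_seed(spec$seed, {
    series <- lapply(seq_len(n_animals), function(k) {
      sessions <- lapply(seq_len(spec$grouping), function(j)
        stats::rbinom(spec$n_trials_per_experiment, 1L, spec$ec))
      trial_series(sprintf("sim%02d", k), sessions, NA_real_, species)
    })
    cohort(series, drug = "bernoulli-null", concentration = spec$ec,
           unit = "response probability",
           label = sprintf("Bernoulli ec=%.3f", spec$ec))
  })
}

#' Mann-Whitney U test with the min-U reporting convention
#'
#' U statistics are computed from midranks (ties allowed); the
#' reported statistic is min(U_x, U_y), matching the magnitudes
#' conventionally printed for small samples. The p-value is exact for
#' small untied samples and uses the normal approximation with tie
#' correction otherwise.
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative \code{"two.sided"} (default), \code{"less"} or
#'   \code{"greater"} (refers to \code{x} relative to \code{y}).
#' @return An object of class \code{"test_result"}.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$statistic  # U = 0
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_x <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_y <- n1 * n2 - u_x
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative)$p.value)
  test_result("Mann-Whitney U", min(u_x, u_y), n1, n2, p, alternative,
              extra = list(u_x = u_x, u_y = u_y))
}

#' Brown-Forsythe test for equal variances
#'
#' One-way analysis of variance on absolute deviations from the group
#' medians. Returns F with (k - 1, N - k) degrees of freedom. When all
#' deviations are zero (identical values within every group) F is
#' reported as 0 with p = 1.
#'
#' @param groups A list of numeric samples, each with >= 2 values.
#' @return An object of class \code{"test_result"} (two-sided F).
#' @export
brown_forsythe <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least two groups")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) < 2L))
    stop("every group needs at least 2 values")
  z <- unlist(lapply(groups, function(g) abs(g - stats::median(g))))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  k <- length(groups); n <- length(z)
  if (all(z == 0))
    return(test_result("Brown-Forsythe F", 0, lengths(groups)[1L],
                       lengths(groups)[2L], 1, "two.sided",
                       extra = list(df1 = k - 1L, df2 = n - k)))
  av <- stats::anova(stats::lm(z ~ g))
  test_result("Brown-Forsythe F", av$`F value`[1L],
              lengths(groups)[1L], lengths(groups)[2L],
              av$`Pr(>F)`[1L], "two.sided",
              extra = list(df1 = av$Df[1L], df2 = av$Df[2L]))
}

test_result <- function(statistic_name, statistic, n1, n2, p, sidedness,
                        extra = list()) {
  structure(c(list(statistic_name = statistic_name,
                   statistic = as.numeric(statistic),
                   n1 = n1, n2 = n2, p = as.numeric(p),
                   sidedness = sidedness), extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s = %s (n1 = %d, n2 = %d), p = %.4g [%s]\n",
              x$statistic_name, format(x$statistic), x$n1, x$n2,
              x$p, x$sidedness))
  invisible(x)
}

#' Compare an experimental cohort against its Bernoulli null
#'
#' Runs the three comparisons used to reject state-independence:
#' \enumerate{
#'   \item per-animal across-trial response probabilities,
#'     experimental vs simulated (expected non-significant — the null
#'     is built to match overall drug potency);
#'   \item per-animal transition fractions, experimental vs simulated
#'     (state-dependent behavior shows fewer switches);
#'   \item within the experimental cohort, P(U|U) vs P(U|R)
#'     (inertia: staying unresponsive is more likely after being
#'     unresponsive).
#' }
#' A Brown-Forsythe comparison of response-probability variances is
#' included as a fourth entry, testing whether inter-animal spread
#' exceeds finite-sample spread under the null.
#'
#' @param experimental A \code{\link{cohort}}.
#' @param spec A \code{\link{bernoulli_spec}}; if \code{NULL}, built
#'   from the experimental cohort's own design and overall response
#'   probability.
#' @param cross_session Passed to \code{\link{markov_fit}}.
#' @return An object of class \code{"cohort_comparison"}: the three
#'   \code{test_result}s (\code{response_probability},
#'   \code{transition_fraction}, \code{conditionals}), the
#'   Brown-Forsythe result (\code{variability}), and the per-animal
#'   summary tables of both cohorts.
#' @export
compare_cohorts <- function(experimental, spec = NULL,
                            cross_session = FALSE) {
  stopifnot(inherits(experimental, "cohort"))
  exp_tab <- markov_summary_table(experimental, cross_session)
  if (is.null(spec)) {
    s1 <- experimental$series[[1L]]
    spec <- bernoulli_spec(
      ec = mean(unlist(lapply(experimental$series, pooled_trials,
                              drop_na = TRUE))),
      n_experiments = length(experimental$series) * length(s1$sessions),
      n_trials_per_experiment = max(lengths(s1$sessions)),
      grouping = length(s1$sessions))
  }
  sim <- simulate_bernoulli(spec, species = experimental$series[[1L]]$species)
  sim_tab <- markov_summary_table(sim, cross_session)
  res <- list(
    response_probability = mann_whitney_u(sim_tab$response_prob,
                                          exp_tab$response_prob),
    transition_fraction = mann_whitney_u(sim_tab$transition_fraction,
                                         exp_tab$transition_fraction),
    conditionals = mann_whitney_u(exp_tab$p_u_given_r,
                                  exp_tab$p_u_given_u),
    variability = brown_forsythe(list(sim_tab$response_prob,
                                      exp_tab$response_prob)),
    experimental = exp_tab, simulated = sim_tab, spec = spec)
  class(res) <- "cohort_comparison"
  res
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("Experimental cohort vs Bernoulli null\n")
  cat("  response probabilities:  "); print(x$response_probability)
  cat("  transition fractions:    "); print(x$transition_fraction)
  cat("  P(U|R) vs P(U|U):        "); print(x$conditionals)
  cat("  variance of resp. prob.: "); print(x$variability)
  invisible(x)
}
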