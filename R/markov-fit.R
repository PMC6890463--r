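#' Construct a two-state transition probability matrix
#'
#' The matrix M = rbind(c(a, 1 - a), c(1 - b, b)) over states
#' R (responsive) and U (unresponsive), where a = P(R|R) is the
#' probability of staying responsive and b = P(U|U) of staying
#' unresponsive. A diagonal is \code{NA} (explicitly undefined) when
#' its source state was never observed.
#'
#' @param a P(R|R) in [0, 1] or \code{NA}.
#' @param b P(U|U) in [0, 1] or \code{NA}.
#' @param n_rr,n_ru,n_uu,n_ur Consecutive-pair counts behind the
#'   estimates (0 when the matrix is specified rather than estimated).
#' @return An object of class \code{"transition_matrix"}.
#' @export
transition_matrix <- function(a, b, n_rr = 0L, n_ru = 0L,
                              n_uu = 0L, n_ur = 0L) {
  for (p in list(a, b))
    if (!is.na(p) && (p < 0 || p > 1))
      stop("diagonal probabilities must lie in [0, 1]")
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 n_rr = as.integer(n_rr), n_ru = as.integer(n_ru),
                 n_uu = as.integer(n_uu), n_ur = as.integer(n_ur)),
            class = "transition_matrix")
}

#' @export
as.matrix.transition_matrix <- function(x, ...) {
  m <- rbind(c(x$a, 1 - x$a), c(1 - x$b, x$b))
  dimnames(m) <- list(from = c("R", "U"), to = c("R", "U"))
  m
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Two-state transition probability matrix\n")
  print(round(as.matrix(x), 4))
  cat(sprintf("pairs: RR=%d RU=%d UU=%d UR=%d\n",
              x$n_rr, x$n_ru, x$n_uu, x$n_ur))
  invisible(x)
}

# Consecutive-trial pairs of a series: a 2-column matrix (from, to).
# A pair is valid when both trials are non-missing and, unless
# cross_session, lie in the same session. A missing trial breaks the
# chain: no pair spans it.
series_pairs <- function(s, cross_session = FALSE) {
  stopifnot(inherits(s, "trial_series"))
  blocks <- if (cross_session) list(pooled_trials(s)) else s$sessions
  out <- lapply(blocks, function(x) {
    if (length(x) < 2L) return(NULL)
    from <- x[-length(x)]
    to <- x[-1L]
    ok <- !is.na(from) & !is.na(to)
    cbind(from = from[ok], to = to[ok])
  })
  do.call(rbind, out)
}

#' Fit a two-state Markov chain to a binary trial series
#'
#' Estimates the transition probability matrix by counting consecutive
#' trial pairs: a = P(R|R) is the fraction of pairs starting responsive
#' that stay responsive, b = P(U|U) the fraction starting unresponsive
#' that stay unresponsive. Also reports the across-trial response
#' probability, the empirical transition (state-switch) fraction, and
#' the conditional probabilities P(U|R) = 1 - a and P(U|U) = b that
#' quantify resistance to state transitions.
#'
#' By default pairs do not span session boundaries (mouse exposures are
#' days apart); set \code{cross_session = TRUE} to chain sessions.
#' A missing trial never contributes a pair.
#'
#' @param s A \code{\link{trial_series}}.
#' @param cross_session Logical; allow pairs to span session boundaries.
#' @return An object of class \code{"markov_fit"} with components
#'   \code{matrix} (a \code{\link{transition_matrix}}),
#'   \code{response_probability}, \code{transition_fraction},
#'   \code{p_u_given_r}, \code{p_u_given_u}, \code{n_pairs},
#'   and the input \code{series}.
#' @seealso \code{\link{stationary_response_probability}},
#'   \code{\link{spectral_gap}}, \code{\link{extract_dwell_times}}
#' @examples
#' s <- trial_series("m1", c(1, 1, 0, 0, 1))
#' fit <- markov_fit(s)
#' coef(fit)          # a = 0.5, b = 0.5
#' @export
markov_fit <- function(s, cross_session = FALSE) {
  pairs <- series_pairs(s, cross_session)
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop("series '", s$animal_id,
         "' has no valid consecutive-trial pairs")
  n_rr <- sum(pairs[, 1L] == 1L & pairs[, 2L] == 1L)
  n_ru <- sum(pairs[, 1L] == 1L & pairs[, 2L] == 0L)
  n_uu <- sum(pairs[, 1L] == 0L & pairs[, 2L] == 0L)
  n_ur <- sum(pairs[, 1L] == 0L & pairs[, 2L] == 1L)
  a <- if (n_rr + n_ru > 0L) n_rr / (n_rr + n_ru) else NA_real_
  b <- if (n_uu + n_ur > 0L) n_uu / (n_uu + n_ur) else NA_real_
  x <- pooled_trials(s, drop_na = TRUE)
  structure(
    list(matrix = transition_matrix(a, b, n_rr, n_ru, n_uu, n_ur),
         response_probability = mean(x),
         transition_fraction = (n_ru + n_ur) / nrow(pairs),
         p_u_given_r = if (is.na(a)) NA_real_ else 1 - a,
         p_u_given_u = b,
         n_pairs = nrow(pairs),
         cross_session = cross_session,
         series = s,
         call = match.call()),
    class = "markov_fit")
}

#' @export
print.markov_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-state Markov fit: animal '%s' (%d valid pairs)\n",
              x$series$animal_id, x$n_pairs))
  cat(sprintf("  P(R|R) = %s   P(U|U) = %s\n",
              format(round(x$matrix$a, digits)),
              format(round(x$matrix$b, digits))))
  cat(sprintf("  response probability = %.3f, transition fraction = %.3f\n",
              x$response_probability, x$transition_fraction))
  invisible(x)
}

#' @export
coef.markov_fit <- function(object, ...) {
  c(a = object$matrix$a, b = object$matrix$b)
}

#' @export
summary.markov_fit <- function(object, ...) {
  m <- object$matrix
  defined <- !is.na(m$a) && !is.na(m$b)
  sg <- if (defined) spectral_gap(m) else
    list(trace = NA_real_, lambda2 = NA_real_, gap = NA_real_)
  stat <- if (defined && m$a + m$b < 2)
    stationary_response_probability(m) else NA_real_
  dw <- extract_dwell_times(object$series)
  structure(
    list(fit = object, spectral = sg, stationary = stat, dwell = dw),
    class = "summary.markov_fit")
}

#' @export
print.summary.markov_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  trace a+b = %s, lambda2 = %s, spectral gap = %s\n",
              format(round(x$spectral$trace, 4)),
              format(round(x$spectral$lambda2, 4)),
              format(round(x$spectral$gap, 4))))
  cat(sprintf("  stationary response probability = %s\n",
              format(round(x$stationary, 4))))
  cat(sprintf("  complete dwells: %d responsive, %d unresponsive (%d censored)\n",
              length(x$dwell$responsive), length(x$dwell$unresponsive),
              x$dwell$censored_responsive + x$dwell$censored_unresponsive))
  invisible(x)
}

#' Predicted response probability k trials ahead
#'
#' Propagates the state distribution k steps through the fitted matrix.
#'
#' @param object A \code{\link{markov_fit}}.
#' @param n_ahead Number of trials ahead (vectorized).
#' @param from Starting condition: \code{"R"}, \code{"U"} or
#'   \code{"stationary"}.
#' @param ... Unused.
#' @return Numeric vector of P(responsive) after each horizon.
#' @export
predict.markov_fit <- function(object, n_ahead = 1L,
                               from = c("stationary", "R", "U"), ...) {
  from <- match.arg(from)
  m <- as.matrix(object$matrix)
  if (anyNA(m)) stop("prediction requires both diagonals defined")
  p0 <- switch(from,
               R = c(1, 0), U = c(0, 1),
               stationary = {
                 pr <- stationary_response_probability(object$matrix)
                 c(pr, 1 - pr)
               })
  vapply(n_ahead, function(k) {
    p <- p0
    if (k > 0) for (j in seq_len(k)) p <- p %*% m
    as.numeric(p[1L])
  }, numeric(1))
}

#' One-step-ahead Pearson residuals
#'
#' For every valid consecutive pair, the residual of the observed next
#' state against the fitted conditional probability of responding.
#'
#' @param object A \code{\link{markov_fit}}.
#' @param ... Unused.
#' @return Numeric vector, one value per valid pair.
#' @export
residuals.markov_fit <- function(object, ...) {
  pairs <- series_pairs(object$series, object$cross_session)
  p_hat <- ifelse(pairs[, 1L] == 1L, object$matrix$a,
                  1 - object$matrix$b)
  v <- p_hat * (1 - p_hat)
  (pairs[, 2L] - p_hat) / sqrt(pmax(v, .Machine$double.eps))
}

#' Simulate new trial series from a fitted chain
#'
#' @param object A \code{\link{markov_fit}} (both diagonals defined).
#' @param nsim Number of series to simulate.
#' @param seed Optional integer seed; the caller's RNG stream is left
#'   untouched when given.
#' @param n_sessions,trials_per_session Design of the simulated series;
#'   default mirrors the fitted series.
#' @param ... Unused.
#' @return A list of \code{\link{trial_series}} (length \code{nsim}).
#' @export
simulate.markov_fit <- function(object, nsim = 1, seed = NULL,
                                n_sessions = NULL,
                                trials_per_session = NULL, ...) {
  m <- object$matrix
  if (is.na(m$a) || is.na(m$b))
    stop("simulation requires both diagonals defined")
  s <- object$series
  if (is.null(n_sessions)) n_sessions <- length(s$sessions)
  if (is.null(trials_per_session))
    trials_per_session <- max(lengths(s$sessions))
  with_seed(seed, {
    lapply(seq_len(nsim), function(k)
      simulate_markov_series(
        m$a, m$b, n_sessions, trials_per_session,
        animal_id = sprintf("%s_sim%d", s$animal_id, k),
        species = s$species,
        inter_trial_interval = s$inter_trial_interval))
  })
}

#' Simulate a two-state Markov trial series
#'
#' Forward-simulates the chain with diagonals (a, b); each session
#' starts from the chain's stationary distribution.
#'
#' @param a,b Transition-matrix diagonals, both defined, not both 1.
#' @param n_sessions,trials_per_session Design.
#' @param animal_id,species,inter_trial_interval Series metadata.
#' @param seed Optional integer seed.
#' @return A \code{\link{trial_series}}.
#' @export
simulate_markov_series <- function(a, b, n_sessions = 1L,
                                   trials_per_session = 40L,
                                   animal_id = "sim",
                                   species = "mouse",
                                   inter_trial_interval = NA_real_,
                                   seed = NULL) {
  if (is.na(a) || is.na(b)) stop("both diagonals must be defined")
  if (a == 1 && b == 1)
    stop("a = b = 1 defines two absorbing states; cannot simulate a mixing chain")
  p_stat <- (1 - b) / (2 - a - b)
  with_seed(seed, {
    sessions <- lapply(seq_len(n_sessions), function(k) {
      x <- integer(trials_per_session)
      x[1L] <- stats::rbinom(1L, 1L, p_stat)
      if (trials_per_session > 1L)
        for (t in 2L:trials_per_session) {
          p_resp <- if (x[t - 1L] == 1L) a else 1 - b
          x[t] <- stats::rbinom(1L, 1L, p_resp)
        }
      x
    })
    trial_series(animal_id, sessions, inter_trial_interval, species)
  })
}

#' @export
plot.markov_fit <- function(x, ...) {
  s <- x$series
  trials <- pooled_trials(s)
  graphics::plot(seq_along(trials), trials, type = "s",
                 xlab = "trial", ylab = "response",
                 yaxt = "n", main = paste("Responses:", s$animal_id), ...)
  graphics::axis(2, at = c(0, 1), labels = c("U", "R"))
  cum <- cumsum(lengths(s$sessions))
  if (length(cum) > 1L)
    graphics::abline(v = cum[-length(cum)] + 0.5, lty = 3, col = "grey50")
  invisible(x)
}

#' Stationary (equilibrium) response probability of a fitted chain
#'
#' The chain's equilibrium distribution gives the long-run probability
#' that the animal responds: (1 - b) / (2 - a - b).
#'
#' @param m A \code{\link{transition_matrix}} or \code{\link{markov_fit}}.
#' @return Probability in [0, 1].
#' @examples
#' stationary_response_probability(transition_matrix(0.8, 0.6))  # 2/3
#' @export
stationary_response_probability <- function(m) {
  m <- as_transition_matrix(m)
  if (is.na(m$a) || is.na(m$b))
    stop("both diagonals must be defined")
  if (m$a + m$b >= 2)
    stop("a = b = 1: two absorbing states, no unique equilibrium")
  (1 - m$b) / (2 - m$a - m$b)
}

as_transition_matrix <- function(m) {
  if (inherits(m, "markov_fit")) m <- m$matrix
  stopifnot(inherits(m, "transition_matrix"))
  m
}

#' Empirical transition fraction of a trial series
#'
#' The fraction of valid consecutive-trial pairs whose two states
#' differ — the per-pair probability of a state switch, the quantity
#' that is depressed relative to a Bernoulli process when responses
#' show inertia.
#'
#' @param s A \code{\link{trial_series}} or \code{\link{markov_fit}}.
#' @param cross_session Passed to pair extraction (ignored for fits).
#' @return Fraction in [0, 1].
#' @export
transition_fraction <- function(s, cross_session = FALSE) {
  if (inherits(s, "markov_fit")) return(s$transition_fraction)
  pairs <- series_pairs(s, cross_session)
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop("no valid consecutive-trial pairs")
  mean(pairs[, 1L] != pairs[, 2L])
}

#' Trace, second eigenvalue and spectral gap of a two-state chain
#'
#' The eigenvalues of M are 1 and a + b - 1; the spectral gap
#' 2 - a - b sets the mixing time toward the equilibrium response
#' probability. A conserved trace across individuals means a conserved
#' mixing time despite differing sensitivities.
#'
#' @param m A \code{\link{transition_matrix}} or \code{\link{markov_fit}}.
#' @return List with \code{trace}, \code{lambda2} and \code{gap}.
#' @export
spectral_gap <- function(m) {
  m <- as_transition_matrix(m)
  if (is.na(m$a) || is.na(m$b))
    stop("both diagonals must be defined")
  list(trace = m$a + m$b, lambda2 = m$a + m$b - 1, gap = 2 - m$a - m$b)
}

#' Extract dwell times from a trial series
#'
#' A dwell is a maximal run of one state. Runs flanked on both sides by
#' the opposite state within one session are complete; runs touching a
#' session edge or a missing trial are censored (their length is not
#' known) and only counted.
#'
#' @param s A \code{\link{trial_series}}.
#' @return An object of class \code{"dwell_times"}: complete dwell
#'   lengths per state plus censored-run counts.
#' @examples
#' extract_dwell_times(trial_series("m", c(1, 1, 0, 0, 0, 1)))
#' @export
extract_dwell_times <- function(s) {
  stopifnot(inherits(s, "trial_series"))
  resp <- integer(0); unresp <- integer(0)
  cens_r <- 0L; cens_u <- 0L
  for (sess in s$sessions) {
    # missing trials split a session into independently censored chunks
    chunks <- split(sess, cumsum(is.na(sess)))
    for (ch in chunks) {
      ch <- ch[!is.na(ch)]
      if (!length(ch)) next
      r <- rle(ch)
      k <- length(r$lengths)
      for (j in seq_len(k)) {
        len <- r$lengths[j]; val <- r$values[j]
        if (j == 1L || j == k) {      # touches an edge -> censored
          if (val == 1L) cens_r <- cens_r + 1L else cens_u <- cens_u + 1L
        } else if (val == 1L) {
          resp <- c(resp, len)
        } else {
          unresp <- c(unresp, len)
        }
      }
    }
  }
  structure(list(responsive = resp, unresponsive = unresp,
                 censored_responsive = cens_r,
                 censored_unresponsive = cens_u),
            class = "dwell_times")
}

#' @export
print.dwell_times <- function(x, ...) {
  cat(sprintf("Dwell times: %d complete responsive, %d complete unresponsive, %d censored\n",
              length(x$responsive), length(x$unresponsive),
              x$censored_responsive + x$censored_unresponsive))
  invisible(x)
}

#' Geometric (discrete-exponential) dwell leave rate
#'
#' Maximum-likelihood per-trial leave rate for geometric dwell
#' lengths: n / sum(dwells). Complete dwells only; censored runs are
#' discarded.
#'
#' @param dwells Vector of complete dwell lengths (trials), all >= 1.
#' @return Leave rate in (0, 1].
#' @examples
#' fit_dwell_rate(c(2, 2, 4))  # 0.375
#' @export
fit_dwell_rate <- function(dwells) {
  if (inherits(dwells, "dwell_times"))
    stop("pass one state's complete dwell lengths, e.g. x$responsive")
  if (!length(dwells)) stop("no complete dwells to fit")
  if (any(dwells < 1)) stop("dwell lengths must be >= 1 trial")
  length(dwells) / sum(dwells)
}

#' Within-session autocorrelation of a binary trial series
#'
#' Mean-subtracted normalized autocorrelation at lags 1..max_lag, with
#' products only for trial pairs inside one session (no pair spans a
#' session boundary or a missing trial). For a two-state chain the
#' analytic lag-1 value is a + b - 1 (the second eigenvalue). The
#' white-noise band is +/- 1.96 / sqrt(N_k) with N_k the number of
#' contributing pairs at lag k.
#'
#' @param s A \code{\link{trial_series}}.
#' @param max_lag Largest lag in trials.
#' @return Data frame with columns \code{lag}, \code{acf},
#'   \code{n_pairs}, \code{band}.
#' @export
response_autocorrelation <- function(s, max_lag = 20L) {
  stopifnot(inherits(s, "trial_series"))
  x_all <- pooled_trials(s, drop_na = TRUE)
  if (length(x_all) < 2L) stop("need at least two non-missing trials")
  mu <- mean(x_all)
  v <- mean((x_all - mu)^2)
  if (v == 0) stop("constant series has zero variance; autocorrelation undefined")
  out <- lapply(seq_len(max_lag), function(k) {
    num <- 0; n <- 0L
    for (sess in s$sessions) {
      if (length(sess) <= k) next
      a <- sess[seq_len(length(sess) - k)]
      b <- sess[(k + 1L):length(sess)]
      ok <- !is.na(a) & !is.na(b)
      num <- num + sum((a[ok] - mu) * (b[ok] - mu))
      n <- n + sum(ok)
    }
    data.frame(lag = k, acf = if (n > 0L) (num / n) / v else NA_real_,
               n_pairs = n,
               band = if (n > 0L) 1.96 / sqrt(n) else NA_real_)
  })
  do.call(rbind, out)
}

#' Steady-state check: trial index vs population response probability
#'
#' Pearson correlation between trial index and the across-animal mean
#' response at that index. An r near zero (p near 1) indicates the
#' population is at behavioral steady state over the analysis window.
#'
#' @param c A \code{\link{cohort}}; sessions are concatenated in order
#'   so trial index runs over the full design (e.g. 1..160 for mice).
#' @return List with \code{r}, \code{p_value}, \code{n_trials} and the
#'   per-index mean vector \code{prp}.
#' @export
steady_state_check <- function(c) {
  stopifnot(inherits(c, "cohort"))
  mat <- sapply(c$series, pooled_trials)
  if (is.list(mat)) stop("all animals must have the same total trial count")
  prp <- rowMeans(mat, na.rm = TRUE)
  if (length(prp) < 3L) stop("need at least 3 trial indices")
  ct <- stats::cor.test(seq_along(prp), prp)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       n_trials = length(prp), prp = prp)
}

#' Per-animal Markov summary table for a cohort
#'
#' One row per animal: transition-matrix diagonals, pair count,
#' across-trial response probability, transition fraction, the two
#' conditionals, trace and spectral gap.
#'
#' @param c A \code{\link{cohort}}.
#' @param cross_session Passed to \code{\link{markov_fit}}.
#' @param path Optional CSV output path.
#' @return A data.frame (written to \code{path} if given).
#' @export
markov_summary_table <- function(c, cross_session = FALSE, path = NULL) {
  stopifnot(inherits(c, "cohort"))
  rows <- lapply(c$series, function(s) {
    f <- markov_fit(s, cross_session)
    m <- f$matrix
    data.frame(animal_id = s$animal_id, a = m$a, b = m$b,
               n_pairs = f$n_pairs,
               response_prob = f$response_probability,
               transition_fraction = f$transition_fraction,
               p_u_given_u = f$p_u_given_u,
               p_u_given_r = f$p_u_given_r,
               trace = m$a + m$b, gap = 2 - m$a - m$b,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
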