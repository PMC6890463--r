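#' Run a named analysis recipe
#'
#' Orchestrates the package's modules into the standard analyses:
#' \describe{
#'   \item{steady_state}{steady-state check + population response
#'     probability of a cohort (needs \code{cohort}).}
#'   \item{bernoulli}{three-way comparison of a cohort against its
#'     matched Bernoulli null (needs \code{cohort}; optional
#'     \code{spec}).}
#'   \item{plane}{(P(U|U), P(R|R)) plane, diagonal correlation and
#'     PCA (needs \code{cohort} or precomputed \code{points}).}
#'   \item{stability}{epoch split (first vs second half of sessions),
#'     common-axis stability correlation and permutation test (needs
#'     \code{cohort}; optional \code{n_perm}).}
#'   \item{decoding}{population densities, overlap and Bayesian
#'     posterior for two cohorts; per-animal bootstrap overlaps when
#'     ids match (needs \code{cohort_a}, \code{cohort_b}).}
#'   \item{sweep}{drug-effect x noise sweep of the bistable landscape
#'     (optional \code{i_values}, \code{sigma_values}, \code{base}).}
#'   \item{hill}{jackknifed constrained Hill fit (needs \code{data},
#'     a dose-response data.frame).}
#' }
#'
#' Every report embeds the parameter echo, a config hash and the seed;
#' identical configuration and seed reproduce the report exactly.
#'
#' @param recipe Recipe name.
#' @param ... Recipe arguments (see above).
#' @param seed Optional integer seed for stochastic recipes.
#' @param out_dir Optional directory; when given, a JSON report (and
#'   CSV tables where natural) is written there.
#' @return A list of class \code{"stochanest_report"}.
#' @export
run_recipe <- function(recipe = c("steady_state", "bernoulli", "plane",
                                  "stability", "decoding", "sweep",
                                  "hill"),
                       ..., seed = NULL, out_dir = NULL) {
  recipe <- match.arg(recipe)
  args <- list(...)
  results <- switch(
    recipe,
    steady_state = {
      co <- need_arg(args, "cohort", "cohort")
      ck <- steady_state_check(co)
      list(r = ck$r, p_value = ck$p_value, n_trials = ck$n_trials,
           prp_mean = mean(ck$prp), prp_sd = stats::sd(ck$prp))
    },
    bernoulli = {
      co <- need_arg(args, "cohort", "cohort")
      spec <- args$spec
      if (!is.null(spec) && !is.null(seed)) spec$seed <- seed
      cmp <- if (is.null(spec)) with_seed(seed, compare_cohorts(co))
             else compare_cohorts(co, spec)
      list(response_probability = unclass(cmp$response_probability),
           transition_fraction = unclass(cmp$transition_fraction),
           conditionals = unclass(cmp$conditionals),
           variability = unclass(cmp$variability))
    },
    plane = {
      pp <- if (!is.null(args$points)) args$points
            else plane_points(need_arg(args, "cohort", "cohort"))
      dc <- diagonal_correlation(pp)
      ax <- pca_plane(pp)
      list(r = dc$r, p_value = dc$p_value,
           variance_explained = ax$variance_explained,
           n_animals = nrow(pp),
           n_excluded = attr(pp, "n_excluded"),
           table = data.frame(pp,
                              pc1_projection = unname(ax$projections)))
    },
    stability = {
      co <- need_arg(args, "cohort", "cohort")
      eps <- split_epochs(co)
      p1 <- plane_points(eps$first, "first epoch")
      p2 <- plane_points(eps$second, "second epoch")
      # an animal with an undefined diagonal in either epoch drops out
      common <- intersect(p1$animal_id, p2$animal_id)
      n_dropped <- length(co$series) - length(common)
      keep <- function(p) structure(
        data.frame(p)[p$animal_id %in% common, ],
        class = c("plane_points", "data.frame"))
      p1 <- keep(p1); p2 <- keep(p2)
      sc <- stability_correlation(p1, p2)
      n_perm <- if (is.null(args$n_perm)) 10000L else args$n_perm
      pt <- permutation_stability_test(p1, p2, n_perm, seed)
      list(r = sc$r, p_value = sc$p_value,
           permutation_p = pt$p_value, n_perm = n_perm,
           n_animals = length(common), n_excluded = n_dropped,
           projections = sc$projections)
    },
    decoding = {
      ca <- need_arg(args, "cohort_a", "cohort")
      cb <- need_arg(args, "cohort_b", "cohort")
      fa <- population_response_density(ca)
      fb <- population_response_density(cb)
      post <- bayes_posterior(fa, fb)
      out <- list(population_overlap = overlap_coefficient(fa, fb),
                  posterior_defined_fraction =
                    mean(!is.na(post$posterior)))
      if (setequal(animal_ids(ca), animal_ids(cb))) {
        n_boot <- if (is.null(args$n_boot)) 1000L else args$n_boot
        boot_size <- if (is.null(args$boot_size)) 20L else args$boot_size
        ov <- per_animal_overlap_summary(ca, cb, n_boot, boot_size,
                                         seed)
        out$per_animal <- ov
      }
      out
    },
    sweep = {
      base <- if (is.null(args$base)) landscape_params() else args$base
      if (!is.null(seed)) base$seed <- seed
      i_values <- if (is.null(args$i_values))
        seq(0.3, 0.7, by = 0.1) else args$i_values
      sigma_values <- if (is.null(args$sigma_values))
        c(0.1, 0.2, 0.4, 0.8, 1.6) else args$sigma_values
      list(table = landscape_sweep(i_values, sigma_values, base))
    },
    hill = {
      d <- need_arg(args, "data", "data.frame")
      constraints <- if ("constraints" %in% names(args))
        args$constraints else hill_anchor()
      jackknife_hill(d, constraints)
    })
  config <- args[!vapply(args, is.object_like, logical(1))]
  report <- list(recipe = recipe, seed = seed, config = config,
                 config_hash = config_hash(c(list(recipe = recipe,
                                                  seed = seed), config)),
                 results = results)
  class(report) <- "stochanest_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

need_arg <- function(args, name, what) {
  x <- args[[name]]
  if (is.null(x)) stop("recipe requires argument '", name, "'")
  if (what == "cohort" && !inherits(x, "cohort"))
    stop("'", name, "' must be a cohort")
  if (what == "data.frame" && !is.data.frame(x))
    stop("'", name, "' must be a data.frame")
  x
}

is.object_like <- function(x) {
  is.list(x) && !is.data.frame(x) && !is.null(attr(x, "class"))
}

# Split each animal's sessions into a first-half and second-half epoch
# (exposures 1-2 vs 3-4 in the mouse design; first vs second half of
# the single zebrafish session).
split_epochs <- function(co) {
  stopifnot(inherits(co, "cohort"))
  halves <- lapply(co$series, function(s) {
    if (length(s$sessions) >= 2L) {
      k <- length(s$sessions) %/% 2L
      list(first = s$sessions[seq_len(k)],
           second = s$sessions[(k + 1L):length(s$sessions)])
    } else {
      x <- s$sessions[[1L]]
      k <- length(x) %/% 2L
      list(first = list(x[seq_len(k)]),
           second = list(x[(k + 1L):length(x)]))
    }
  })
  mk <- function(which) cohort(
    lapply(seq_along(co$series), function(j) {
      s <- co$series[[j]]
      trial_series(s$animal_id, halves[[j]][[which]],
                   s$inter_trial_interval, s$species)
    }),
    co$drug, co$concentration, co$unit,
    paste(co$label, which, "epoch"))
  list(first = mk("first"), second = mk("second"))
}

# Polynomial rolling hash (mod 2^31 - 1) over the deparsed config;
# enough to fingerprint a run.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.stochanest_report <- function(x, ...) {
  cat(sprintf("Recipe '%s' (seed %s, config %s)\n", x$recipe,
              if (is.null(x$seed)) "none" else x$seed, x$config_hash))
  scalars <- Filter(function(v) is.numeric(v) && length(v) == 1L,
                    x$results)
  for (nm in names(scalars))
    cat(sprintf("  %s = %s\n", nm, format(signif(scalars[[nm]], 5))))
  invisible(x)
}

write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  slim <- report
  slim$results <- lapply(report$results, function(v) {
    if (is.data.frame(v)) NULL else v
  })
  slim$results <- Filter(Negate(is.null), slim$results)
  jsonlite::write_json(
    slim, file.path(out_dir, paste0(report$recipe, "_report.json")),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  for (nm in names(report$results)) {
    v <- report$results[[nm]]
    if (is.data.frame(v))
      utils::write.csv(v, file.path(out_dir,
                                    paste0(report$recipe, "_", nm, ".csv")),
                       row.names = FALSE)
  }
  invisible(report)
}
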