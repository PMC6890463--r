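#' Individual transition matrices as points on the (P(U|U), P(R|R)) plane
#'
#' Each animal's fitted two-state chain is a point (b, a) on the plane
#' spanned by the diagonals P(U|U) and P(R|R). Animals with an
#' undefined diagonal (a state never visited) are excluded and counted.
#'
#' @param x A \code{\link{cohort}}, a list of \code{\link{markov_fit}}s
#'   or \code{\link{transition_matrix}}es, or a data.frame with columns
#'   \code{animal_id}, \code{a}, \code{b} (e.g. from
#'   \code{\link{markov_summary_table}} or a deposited source table).
#' @param label Free-text label.
#' @param cross_session Passed to \code{\link{markov_fit}} for cohorts.
#' @return An object of class \code{"plane_points"}: a data.frame with
#'   columns \code{animal_id}, \code{p_uu} (= b), \code{p_rr} (= a) and
#'   attributes \code{n_excluded}, \code{label}.
#' @export
plane_points <- function(x, label = "", cross_session = FALSE) {
  if (inherits(x, "cohort")) {
    tab <- markov_summary_table(x, cross_session)
  } else if (is.data.frame(x)) {
    if (!all(c("a", "b") %in% names(x)))
      stop("data.frame input needs columns 'a' and 'b'")
    tab <- data.frame(
      animal_id = if ("animal_id" %in% names(x)) as.character(x$animal_id)
                  else sprintf("obs%03d", seq_len(nrow(x))),
      a = x$a, b = x$b, stringsAsFactors = FALSE)
  } else if (is.list(x)) {
    tab <- do.call(rbind, lapply(seq_along(x), function(k) {
      m <- as_transition_matrix(x[[k]])
      id <- if (inherits(x[[k]], "markov_fit"))
        x[[k]]$series$animal_id else sprintf("m%03d", k)
      data.frame(animal_id = id, a = m$a, b = m$b,
                 stringsAsFactors = FALSE)
    }))
  } else stop("unsupported input for plane_points()")
  keep <- !is.na(tab$a) & !is.na(tab$b)
  out <- data.frame(animal_id = tab$animal_id[keep],
                    p_uu = tab$b[keep], p_rr = tab$a[keep],
                    stringsAsFactors = FALSE)
  structure(out, class = c("plane_points", "data.frame"),
            n_excluded = sum(!keep), label = label)
}

#' Correlation between the transition-matrix diagonals across animals
#'
#' Pearson correlation between P(U|U) and P(R|R) across individuals.
#' A strong negative correlation with near-constant sum a + b means
#' inter-individual variability is confined to sensitivity while the
#' noise driving state switches (the spectral gap) is conserved.
#'
#' @param p A \code{\link{plane_points}} object (>= 3 points).
#' @return List with signed Pearson \code{r} and two-sided
#'   \code{p_value}.
#' @export
diagonal_correlation <- function(p) {
  stopifnot(inherits(p, "plane_points"))
  if (nrow(p) < 3L) stop("need at least 3 points")
  if (stats::sd(p$p_uu) == 0 || stats::sd(p$p_rr) == 0)
    stop("zero variance in a coordinate; correlation undefined")
  ct <- stats::cor.test(p$p_uu, p$p_rr)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(p))
}

#' PCA of the transition-probability plane
#'
#' Centered, unscaled PCA of the 2-D points (both axes are
#' probabilities, so no rescaling). PC1 is oriented so that the
#' projection increases with P(U|U) - P(R|R): negative projections are
#' animals that tend to stay responsive, positive projections animals
#' that tend to stay unresponsive.
#'
#' @param p A \code{\link{plane_points}} object (>= 3 points, not all
#'   identical).
#' @return An object of class \code{"pca_plane"} with \code{mean},
#'   unit \code{pc1_direction} (in (p_uu, p_rr) coordinates),
#'   \code{variance_explained} and named \code{projections}.
#' @export
pca_plane <- function(p) {
  stopifnot(inherits(p, "plane_points"))
  if (nrow(p) < 3L) stop("need at least 3 points")
  m <- cbind(p_uu = p$p_uu, p_rr = p$p_rr)
  if (all(apply(m, 2, stats::sd) == 0))
    stop("all points identical; PCA undefined")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  v <- pc$rotation[, 1L]
  # orient: projection grows with p_uu - p_rr
  if (sum(v * c(1, -1)) < 0) v <- -v
  ctr <- pc$center
  proj <- as.numeric((m - matrix(ctr, nrow(m), 2, byrow = TRUE)) %*% v)
  names(proj) <- p$animal_id
  structure(list(mean = ctr, pc1_direction = v,
                 variance_explained = pc$sdev[1L]^2 / sum(pc$sdev^2),
                 projections = proj),
            class = "pca_plane")
}

#' @export
print.pca_plane <- function(x, ...) {
  cat(sprintf("Plane PCA: PC1 = (%.3f, %.3f), %.1f%% of variance, n = %d\n",
              x$pc1_direction[1L], x$pc1_direction[2L],
              100 * x$variance_explained, length(x$projections)))
  invisible(x)
}

# Common PC1 projections of two epochs, axis fit on the pooled points,
# matched by animal id.
common_axis_projections <- function(first, second) {
  stopifnot(inherits(first, "plane_points"), inherits(second, "plane_points"))
  if (!setequal(first$animal_id, second$animal_id) ||
      nrow(first) != nrow(second))
    stop("the two epochs must contain the same animals")
  second <- second[match(first$animal_id, second$animal_id), ]
  pooled <- rbind(data.frame(first), data.frame(second))
  pooled_pp <- structure(pooled, class = c("plane_points", "data.frame"))
  ax <- pca_plane(pooled_pp)
  prj <- function(p) as.numeric(
    (cbind(p$p_uu, p$p_rr) -
       matrix(ax$mean, nrow(p), 2, byrow = TRUE)) %*% ax$pc1_direction)
  data.frame(animal_id = first$animal_id,
             first = prj(first), second = prj(second),
             stringsAsFactors = FALSE)
}

#' Within-individual stability of the transition matrix across epochs
#'
#' Fits one PC1 axis to the pooled points of both epochs, projects each
#' epoch onto it, and correlates the projections of the same animals.
#' A positive correlation means an individual's position on the
#' sensitivity axis is a stable trait.
#'
#' @param first,second \code{\link{plane_points}} for the two epochs
#'   (e.g. exposures 1-2 vs 3-4), same animals.
#' @return List with Pearson \code{r}, two-sided \code{p_value} and the
#'   matched projection table.
#' @export
stability_correlation <- function(first, second) {
  prj <- common_axis_projections(first, second)
  ct <- stats::cor.test(prj$first, prj$second)
  list(r = unname(ct$estimate), p_value = ct$p.value, projections = prj)
}

#' Permutation test of within-individual stability
#'
#' Shuffles the animal pairing between the two epochs \code{n_perm}
#' times and compares the observed projection correlation against the
#' shuffled surrogates. One-sided with the add-one correction:
#' p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm).
#'
#' @param first,second \code{\link{plane_points}} for the two epochs.
#' @param n_perm Number of permutations (>= 100; 10000 in the original
#'   analysis).
#' @param seed Optional integer seed.
#' @return List with \code{p_value}, \code{r_observed} and the vector
#'   \code{r_perm}.
#' @export
permutation_stability_test <- function(first, second, n_perm = 10000L,
                                       seed = NULL) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  prj <- common_axis_projections(first, second)
  r_obs <- stats::cor(prj$first, prj$second)
  with_seed(seed, {
    r_perm <- vapply(seq_len(n_perm), function(k)
      stats::cor(prj$first, sample(prj$second)), numeric(1))
    list(p_value = (1 + sum(r_perm >= r_obs)) / (1 + n_perm),
         r_observed = r_obs, r_perm = r_perm)
  })
}

#' Write a plane CSV
#'
#' Emits \code{animal_id,p_uu,p_rr,pc1_projection}.
#' @param p A \code{\link{plane_points}} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_plane_csv <- function(p, path) {
  ax <- pca_plane(p)
  df <- data.frame(p)
  df$pc1_projection <- ax$projections[df$animal_id]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
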