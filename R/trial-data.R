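#' Construct a trial series
#'
#' A trial series is one animal's ordered binary behavioral record
#' (1 = responsive, 0 = unresponsive, \code{NA} = missing trial),
#' partitioned into sessions. For mice a session is one exposure
#' (40 righting-reflex trials at 3-min intervals); a zebrafish series
#' is a single session of startle-reflex trials at 30-s intervals.
#'
#' @param animal_id Character scalar identifying the animal.
#' @param sessions A list of integer/numeric vectors of 0/1/\code{NA},
#'   or a single vector (treated as one session). Session order is
#'   preserved.
#' @param inter_trial_interval Seconds between trials (180 for the
#'   mouse design, 30 for zebrafish). Informational.
#' @param species \code{"mouse"} or \code{"zebrafish"}.
#' @return An object of class \code{"trial_series"}.
#' @examples
#' s <- trial_series("m1", list(c(1, 1, 0, 0, 1)), 180, "mouse")
#' n_trials(s)
#' @export
trial_series <- function(animal_id, sessions,
                         inter_trial_interval = NA_real_,
                         species = c("mouse", "zebrafish")) {
  species <- match.arg(species)
  if (!is.character(animal_id) || length(animal_id) != 1L || is.na(animal_id))
    stop("'animal_id' must be a single non-missing string")
  if (!is.list(sessions)) sessions <- list(sessions)
  if (length(sessions) == 0L) stop("at least one session is required")
  sessions <- lapply(seq_along(sessions), function(k) {
    x <- sessions[[k]]
    if (!is.numeric(x) && !is.logical(x) && !is.integer(x))
      stop("session ", k, ": responses must be numeric 0/1/NA")
    x <- as.integer(x)
    bad <- which(!is.na(x) & !(x %in% c(0L, 1L)))
    if (length(bad))
      stop("session ", k, ", trial ", bad[1L],
           ": response must be 0, 1 or NA")
    x
  })
  structure(
    list(animal_id = animal_id,
         sessions = sessions,
         inter_trial_interval = inter_trial_interval,
         species = species),
    class = "trial_series")
}

#' @export
print.trial_series <- function(x, ...) {
  n <- n_trials(x)
  cat(sprintf("Trial series '%s' (%s): %d session(s), %d trials (%d missing)\n",
              x$animal_id, x$species, length(x$sessions), n,
              sum(is.na(unlist(x$sessions)))))
  invisible(x)
}

#' Total number of trials in a trial series
#'
#' @param s A \code{trial_series}.
#' @return Integer count, the sum of session lengths (missing trials included).
#' @export
n_trials <- function(s) {
  stopifnot(inherits(s, "trial_series"))
  sum(lengths(s$sessions))
}

#' Pool a trial series across sessions
#'
#' Concatenates the sessions in order into one vector of 0/1/\code{NA}.
#' @param s A \code{trial_series}.
#' @param drop_na Drop missing trials.
#' @return Integer vector.
#' @export
pooled_trials <- function(s, drop_na = FALSE) {
  stopifnot(inherits(s, "trial_series"))
  x <- unlist(s$sessions, use.names = FALSE)
  if (drop_na) x <- x[!is.na(x)]
  x
}

#' Construct a cohort of trial series
#'
#' @param series List of \code{trial_series}; all must share species, and
#'   animal ids must be unique.
#' @param drug Drug name, e.g. \code{"isoflurane"}.
#' @param concentration Numeric concentration.
#' @param unit Concentration unit (\code{"% atm"} for isoflurane,
#'   \code{"uM"} for propofol).
#' @param label Free-text cohort label.
#' @return An object of class \code{"cohort"}.
#' @export
cohort <- function(series, drug = "", concentration = NA_real_,
                   unit = "", label = "") {
  if (!is.list(series) || !length(series) ||
      !all(vapply(series, inherits, logical(1), "trial_series")))
    stop("'series' must be a non-empty list of trial_series objects")
  ids <- vapply(series, `[[`, character(1), "animal_id")
  if (anyDuplicated(ids))
    stop("duplicate animal_id: ", ids[duplicated(ids)][1L])
  sp <- unique(vapply(series, `[[`, character(1), "species"))
  if (length(sp) != 1L)
    stop("all series in a cohort must share one species")
  names(series) <- ids
  structure(
    list(series = series, drug = drug, concentration = concentration,
         unit = unit, label = label),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort '%s': %d %s, %s %s%s\n",
              x$label, length(x$series), x$series[[1L]]$species,
              x$drug, format(x$concentration), x$unit))
  invisible(x)
}

#' Animal identifiers of a cohort
#' @param c A \code{cohort}.
#' @return Character vector.
#' @export
animal_ids <- function(c) {
  stopifnot(inherits(c, "cohort"))
  names(c$series)
}

#' Read a trial-matrix CSV into a cohort
#'
#' The dialect has header \code{animal_id,session,trial_index,response},
#' with \code{response} in \{0, 1, NA\} and \code{trial_index} 1-based
#' within session. Values round-trip bit-exactly through
#' \code{\link{write_trial_csv}}.
#'
#' @param path File path.
#' @param drug,concentration,unit,label Cohort metadata (not stored in
#'   the CSV).
#' @param species,inter_trial_interval Series metadata.
#' @return A \code{\link{cohort}}.
#' @export
read_trial_csv <- function(path, drug = "", concentration = NA_real_,
                           unit = "", label = "",
                           species = c("mouse", "zebrafish"),
                           inter_trial_interval = NA_real_) {
  species <- match.arg(species)
  df <- utils::read.csv(path, colClasses = c(animal_id = "character"),
                        na.strings = "NA")
  need <- c("animal_id", "session", "trial_index", "response")
  if (!all(need %in% names(df)))
    stop("trial CSV must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("trial CSV has an empty data section")
  bad <- which(!is.na(df$response) & !(df$response %in% c(0, 1)))
  if (length(bad))
    stop("malformed response at row ", bad[1L] + 1L,
         " (column 'response'): must be 0, 1 or NA")
  series <- lapply(split(df, df$animal_id), function(d) {
    d <- d[order(d$session, d$trial_index), ]
    trial_series(d$animal_id[1L],
                 lapply(split(d$response, d$session), as.integer),
                 inter_trial_interval, species)
  })
  # split() sorts animal ids lexicographically; preserve file order
  series <- series[unique(df$animal_id)]
  cohort(unname(series), drug, concentration, unit, label)
}

#' Write a cohort to the trial-matrix CSV dialect
#'
#' @param c A \code{\link{cohort}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_trial_csv <- function(c, path) {
  stopifnot(inherits(c, "cohort"))
  rows <- do.call(rbind, lapply(c$series, function(s) {
    do.call(rbind, lapply(seq_along(s$sessions), function(k) {
      x <- s$sessions[[k]]
      data.frame(animal_id = s$animal_id, session = k,
                 trial_index = seq_along(x), response = x,
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Construct a displacement table
#'
#' Per-trial post-stimulus travel distances (mm) for one zebrafish,
#' one value per tap trial, to be binarized by
#' \code{\link{threshold_displacements}}.
#'
#' @param animal_id Character scalar.
#' @param distances Non-negative numeric vector (mm).
#' @return An object of class \code{"displacement_table"}.
#' @export
displacement_table <- function(animal_id, distances) {
  if (!is.numeric(distances) || !length(distances))
    stop("'distances' must be a non-empty numeric vector")
  if (any(distances < 0, na.rm = TRUE))
    stop("distances must be >= 0 (got ", min(distances, na.rm = TRUE), ")")
  structure(list(animal_id = animal_id, distances = as.numeric(distances)),
            class = "displacement_table")
}

#' Threshold displacements into a binary trial series
#'
#' A trial is responsive (1) iff the post-stimulus distance strictly
#' exceeds the threshold. The default 0.4 mm is roughly one tenth of a
#' 5-dpf larva's body length, chosen where the bimodal displacement
#' histogram dips; distances exactly at the threshold count as
#' unresponsive so the rule is deterministic.
#'
#' @param d A \code{\link{displacement_table}}.
#' @param threshold Positive distance in mm (default 0.4).
#' @param inter_trial_interval Seconds between taps (default 30).
#' @return A single-session zebrafish \code{\link{trial_series}} of the
#'   same length.
#' @examples
#' d <- displacement_table("z1", c(0, 0.39, 0.41, 5))
#' pooled_trials(threshold_displacements(d))  # 0 0 1 1
#' @export
threshold_displacements <- function(d, threshold = 0.4,
                                    inter_trial_interval = 30) {
  stopifnot(inherits(d, "displacement_table"))
  if (!is.numeric(threshold) || threshold <= 0)
    stop("'threshold' must be a positive distance in mm")
  resp <- ifelse(is.na(d$distances), NA_integer_,
                 as.integer(d$distances > threshold))
  trial_series(d$animal_id, list(resp), inter_trial_interval, "zebrafish")
}

#' Read a displacement CSV
#'
#' Dialect: \code{animal_id,trial_index,distance_mm}.
#' @param path File path.
#' @return A named list of \code{\link{displacement_table}} objects.
#' @export
read_displacement_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(animal_id = "character"))
  need <- c("animal_id", "trial_index", "distance_mm")
  if (!all(need %in% names(df)))
    stop("displacement CSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$animal_id), function(d) {
    d <- d[order(d$trial_index), ]
    displacement_table(d$animal_id[1L], d$distance_mm)
  })
  out[unique(df$animal_id)]
}

#' Write displacement tables to CSV
#' @param tables A list of \code{\link{displacement_table}} objects (or one).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_displacement_csv <- function(tables, path) {
  if (inherits(tables, "displacement_table")) tables <- list(tables)
  rows <- do.call(rbind, lapply(tables, function(d)
    data.frame(animal_id = d$animal_id,
               trial_index = seq_along(d$distances),
               distance_mm = d$distances, stringsAsFactors = FALSE)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a plain numeric source-data table
#'
#' Loader for deposited per-figure source-data files: plain CSV, one
#' column per quantity, numeric cells. No interpretation is applied.
#'
#' @param path File path.
#' @return A data.frame of numeric columns.
#' @export
read_source_table <- function(path) {
  df <- utils::read.csv(path)
  nonnum <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(nonnum))
    stop("source table columns must be numeric; offending: ",
         paste(nonnum, collapse = ", "))
  df
}

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is untouched. seed = NULL means "use the
# current stream" (and advance it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer or NULL")
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}
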