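#' Tile an exposure window with fixed-width intervals
#'
#' Builds the participant-specific sequence of half-open day windows
#' `[start, start + width)` from enrollment to delivery. The trailing window
#' is flagged partial when the exposure is not an exact multiple of `width`;
#' a window counts as "completed" only if its full `width` days end on or
#' before delivery.
#'
#' @param enrollment_day Integer day offset of enrollment (0 = consent).
#' @param delivery_day Integer day offset of delivery; must exceed
#'   `enrollment_day`.
#' @param width Window width in days (default 45, chosen to absorb
#'   variability in the timing of monthly prenatal visits).
#' @return An object of class `interval_scheme`: list with `starts`, `ends`
#'   (parallel vectors of window bounds), `n_windows`, `n_completed`,
#'   `has_partial`, `enrollment_day`, `delivery_day`.
#' @examples
#' build_interval_scheme(0, 100)   # two completed windows + partial [90,100)
#' @export
build_interval_scheme <- function(enrollment_day, delivery_day, width = 45L) {
  if (!is_scalar_int(enrollment_day) || !is_scalar_int(delivery_day) ||
      !is_scalar_int(width))
    stop2("enrollment_day, delivery_day and width must be single integers")
  if (width < 1L) stop2("width must be >= 1")
  exposure <- delivery_day - enrollment_day
  if (exposure < 1L)
    stop2("invalid exposure window: delivery_day must exceed enrollment_day")
  n_completed <- exposure %/% width
  has_partial <- (exposure %% width) != 0L
  n_windows <- n_completed + as.integer(has_partial)
  starts <- enrollment_day + width * (seq_len(n_windows) - 1L)
  ends <- pmin(starts + width, delivery_day)
  structure(list(starts = as.integer(starts), ends = as.integer(ends),
                 n_windows = as.integer(n_windows),
                 n_completed = as.integer(n_completed),
                 has_partial = has_partial,
                 enrollment_day = as.integer(enrollment_day),
                 delivery_day = as.integer(delivery_day)),
            class = "interval_scheme")
}

#' @export
print.interval_scheme <- function(x, ...) {
  cat("Interval scheme: days [", x$enrollment_day, ", ", x$delivery_day,
      "], ", x$n_completed, " completed window(s)",
      if (x$has_partial) " + partial", "\n", sep = "")
  invisible(x)
}

consistency_levels <- function() {
  c("consistent", "almost_consistent", "inconsistent", "never")
}

quantity_levels <- function() c("high", "low", "never")

# window index of each event day; days on/after the last start (including
# delivery day itself) fall in the last window
window_index <- function(days, scheme) {
  pmin(findInterval(days, scheme$starts), scheme$n_windows)
}

#' Categorize consistency of use across intervals
#'
#' Classifies a participant's use of a consistency-expected feature (log-in,
#' weight tracker) over their completed 45-day intervals: `consistent` if
#' every completed window contains at least one event, `almost_consistent` if
#' at least half do, `inconsistent` if there is any event but fewer than half
#' of the windows are covered, `never` if there are no events at all. When
#' the exposure is shorter than one full window, the single partial window
#' serves as the denominator.
#'
#' @param event_days Integer vector of event day offsets (may be empty); all
#'   must fall in `[enrollment_day, delivery_day]`.
#' @param scheme An [build_interval_scheme()] result.
#' @return One of `"consistent"`, `"almost_consistent"`, `"inconsistent"`,
#'   `"never"`.
#' @export
categorize_consistency <- function(event_days, scheme) {
  stopifnot(inherits(scheme, "interval_scheme"))
  if (length(event_days) == 0L) return("never")
  if (any(event_days < scheme$enrollment_day |
          event_days > scheme$delivery_day))
    stop2("event days outside the enrollment-delivery window")
  # denominator: completed windows, or the lone partial window if none
  if (scheme$n_completed >= 1L) {
    denom_idx <- seq_len(scheme$n_completed)
  } else {
    denom_idx <- 1L
  }
  hit <- unique(window_index(event_days, scheme))
  frac <- length(intersect(hit, denom_idx)) / length(denom_idx)
  if (frac == 1) "consistent"
  else if (frac >= 0.5) "almost_consistent"
  else "inconsistent"
}

#' Median use among users of a feature
#'
#' The "user median" behind the high/low split of quantity-coded features:
#' the median event count among participants with at least one event. Zero
#' counts (non-users) are excluded before the median is taken; an even number
#' of users yields the midpoint of the two central order statistics.
#'
#' @param counts Non-negative integer vector of per-participant event counts.
#' @return The median of the positive counts.
#' @export
compute_user_median <- function(counts) {
  if (any(counts < 0)) stop2("counts must be non-negative")
  users <- counts[counts > 0]
  if (length(users) == 0L)
    stop2("no users: all counts are zero, the user median is undefined")
  stats::median(users)
}

#' Categorize quantity of use relative to the user median
#'
#' `never` for a zero count, `high` for counts at or above the user median,
#' `low` otherwise.
#'
#' @param count Non-negative integer event count.
#' @param user_median Positive user median (see [compute_user_median()]).
#' @return One of `"high"`, `"low"`, `"never"`.
#' @export
categorize_quantity <- function(count, user_median) {
  if (length(count) != 1L || count < 0)
    stop2("count must be a single non-negative number")
  if (user_median <= 0) stop2("user_median must be positive")
  if (count == 0) "never"
  else if (count >= user_median) "high"
  else "low"
}

engagement_features <- function() {
  c("login", "weight_tracker", "health_info", "blogs", "resources",
    "pa_goal", "diet_goal")
}

consistency_features <- function() c("login", "weight_tracker")

quantity_features <- function() {
  c("health_info", "blogs", "resources", "pa_goal", "diet_goal")
}

validate_roster <- function(roster) {
  req <- c("participant_id", "enrollment_day", "delivery_day")
  missing_cols <- setdiff(req, names(roster))
  if (length(missing_cols))
    stop2("roster is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(roster$participant_id))
    stop2("duplicate participant_id in roster")
  invisible(roster)
}

validate_events <- function(events, roster) {
  req <- c("participant_id", "feature", "day")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols))
    stop2("events table is missing columns: ",
          paste(missing_cols, collapse = ", "))
  bad_feat <- setdiff(unique(as.character(events$feature)),
                      engagement_features())
  if (length(bad_feat))
    stop2("unknown feature label(s): ", paste(bad_feat, collapse = ", "))
  bad_id <- setdiff(unique(as.character(events$participant_id)),
                    as.character(roster$participant_id))
  if (length(bad_id))
    stop2("events reference participants absent from roster: ",
          paste(utils::head(bad_id, 5), collapse = ", "))
  if (any(events$day < 0)) stop2("event days must be non-negative")
  invisible(events)
}

#' Build per-participant engagement profiles from a roster and event log
#'
#' Converts a participant roster and a timestamped feature-use log into the
#' seven categorical engagement indicators: log-in and weight-tracker use are
#' consistency-coded on each participant's own 45-day interval scheme; the
#' five "as needed" features (health-related information, blogs, local
#' resources, physical activity and diet goal-setting) are quantity-coded
#' against feature-specific medians computed among users of that feature.
#' Events falling outside a participant's enrollment-delivery window are
#' dropped (the count of dropped records is attached as an attribute).
#'
#' @param roster Data frame with columns `participant_id`, `enrollment_day`,
#'   `delivery_day` (extra columns are ignored).
#' @param events Data frame with columns `participant_id`, `feature`, `day`.
#'   `feature` must be one of the seven engagement features.
#' @param window_width Interval width in days (default 45).
#' @param reference_medians Optional named numeric vector of user medians for
#'   the five quantity features. When `NULL` (the default) medians are
#'   computed from the data at hand; supplying them makes categorization
#'   reproducible against an external reference (e.g. the synthetic
#'   generator's medians).
#' @return A data frame with `participant_id` and one character column per
#'   indicator, in the order of [engagement_spec()]. Attributes: `medians`
#'   (the per-feature medians used, `NA` for features with no users) and
#'   `n_dropped_events`.
#' @export
build_profiles <- function(roster, events, window_width = 45L,
                           reference_medians = NULL) {
  validate_roster(roster)
  validate_events(events, roster)
  ids <- as.character(roster$participant_id)
  n <- length(ids)

  schemes <- lapply(seq_len(n), function(i)
    build_interval_scheme(roster$enrollment_day[i], roster$delivery_day[i],
                          window_width))
  names(schemes) <- ids

  # keep only events inside each participant's exposure window
  ev_id <- as.character(events$participant_id)
  lo <- roster$enrollment_day[match(ev_id, ids)]
  hi <- roster$delivery_day[match(ev_id, ids)]
  keep <- events$day >= lo & events$day <= hi
  n_dropped <- sum(!keep)
  events <- events[keep, , drop = FALSE]
  ev_id <- ev_id[keep]
  ev_feat <- as.character(events$feature)

  # per-participant event-day lists for consistency features
  profile <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (feat in consistency_features()) {
    sel <- ev_feat == feat
    day_list <- split(events$day[sel], factor(ev_id[sel], levels = ids))
    profile[[feat]] <- vapply(seq_len(n), function(i)
      categorize_consistency(day_list[[i]], schemes[[i]]), character(1))
  }

  # feature-specific user medians, then high/low/never coding
  medians <- stats::setNames(rep(NA_real_, length(quantity_features())),
                             quantity_features())
  for (feat in quantity_features()) {
    sel <- ev_feat == feat
    counts <- as.integer(table(factor(ev_id[sel], levels = ids)))
    med <- if (!is.null(reference_medians)) {
      if (is.na(reference_medians[feat]))
        stop2("reference_medians missing entry for '", feat, "'")
      unname(reference_medians[feat])
    } else if (any(counts > 0)) {
      compute_user_median(counts)
    } else {
      NA_real_  # nobody used the feature; every profile is "never"
    }
    medians[feat] <- med
    profile[[feat]] <- vapply(counts, function(k) {
      if (k == 0) "never" else categorize_quantity(k, med)
    }, character(1))
  }

  profile <- profile[c("participant_id", engagement_spec()$items)]
  attr(profile, "medians") <- medians
  attr(profile, "n_dropped_events") <- n_dropped
  profile
}
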