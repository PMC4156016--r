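# draw one declared level per row: class_idx selects the rho row to sample from
draw_levels <- function(rho, class_idx, levels) {
  P <- rho[class_idx, , drop = FALSE]
  cp <- t(apply(P, 1L, cumsum))
  u <- stats::runif(length(class_idx))
  levels[max.col(u <= cp, ties.method = "first")]
}

validate_prob_table <- function(gamma, rho, spec, what) {
  if (abs(sum(gamma) - 1) > 1e-9 || any(gamma < 0))
    stop2(what, " prevalences must be a probability vector")
  for (it in spec$items) {
    m <- rho[[it]]
    if (is.null(m) || ncol(m) != length(spec$levels[[it]]) ||
        nrow(m) != length(gamma))
      stop2(what, " rho table for '", it, "' has wrong dimensions")
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9))
      stop2(what, " rho rows for '", it, "' must sum to 1")
  }
  invisible(TRUE)
}

#' Configuration of the synthetic cohort generator
#'
#' Bundles everything the generator needs: the four demographic/BMI
#' subgroups with their class-conditional response probabilities, the six
#' engagement-pattern classes with their feature-use probabilities, the
#' exposure range (2 to 9 months between enrollment and delivery), and the
#' reference user medians the event renderer targets for quantity-coded
#' features.
#'
#' @param n Number of participants (>= 1).
#' @param seed Integer seed; the whole bundle is deterministic under
#'   `(config, seed)`.
#' @param subgroup_gamma,subgroup_rho Subgroup prevalences and response
#'   probabilities; default [subgroup_params()].
#' @param engagement_gamma,engagement_rho Engagement-class prevalences and
#'   feature-use probabilities; default [engagement_params()].
#' @param exposure_days Length-2 integer range of exposure durations in days
#'   (default `c(60, 270)`); each participant's is drawn uniformly.
#' @param reference_medians Named positive numerics, the per-feature user
#'   medians the renderer reproduces counts against (defaults: health_info 4,
#'   blogs 4, resources 3, pa_goal 3, diet_goal 3).
#' @param class_probs_by_subgroup Optional 4 x 6 matrix of
#'   subgroup-conditional engagement-class probabilities (rows = subgroups,
#'   rows sum to 1). When supplied, engagement class is drawn conditionally
#'   on subgroup, inducing a class-by-subgroup association for power studies;
#'   by default the two are independent.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n, seed = 1L,
                             subgroup_gamma = subgroup_params()$gamma,
                             subgroup_rho = subgroup_params()$rho,
                             engagement_gamma = engagement_params()$gamma,
                             engagement_rho = engagement_params()$rho,
                             exposure_days = c(60L, 270L),
                             reference_medians = c(health_info = 4, blogs = 4,
                                                   resources = 3, pa_goal = 3,
                                                   diet_goal = 3),
                             class_probs_by_subgroup = NULL) {
  if (!is_scalar_int(n) || n < 1) stop2("n must be a positive integer")
  subgroup_gamma <- subgroup_gamma / sum(subgroup_gamma)
  engagement_gamma <- engagement_gamma / sum(engagement_gamma)
  validate_prob_table(subgroup_gamma, subgroup_rho, subgroup_spec(),
                      "subgroup")
  validate_prob_table(engagement_gamma, engagement_rho, engagement_spec(),
                      "engagement")
  stopifnot(length(exposure_days) == 2L, exposure_days[1] >= 1,
            exposure_days[2] >= exposure_days[1])
  if (any(reference_medians[quantity_features()] <= 0) ||
      anyNA(reference_medians[quantity_features()]))
    stop2("reference_medians must be positive for all five quantity features")
  if (!is.null(class_probs_by_subgroup)) {
    stopifnot(nrow(class_probs_by_subgroup) == length(subgroup_gamma),
              ncol(class_probs_by_subgroup) == length(engagement_gamma),
              all(abs(rowSums(class_probs_by_subgroup) - 1) < 1e-9))
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 subgroup_gamma = subgroup_gamma,
                 subgroup_rho = subgroup_rho,
                 engagement_gamma = engagement_gamma,
                 engagement_rho = engagement_rho,
                 exposure_days = as.integer(exposure_days),
                 reference_medians = reference_medians,
                 class_probs_by_subgroup = class_probs_by_subgroup),
            class = "generator_config")
}

#' Generate a synthetic participant roster
#'
#' Draws each participant's demographic/BMI subgroup from the configured
#' prevalences, then race, ethnicity, income, BMI and age category
#' conditionally independently from that subgroup's response rows (the same
#' local-independence structure the subgroup LCA assumes), and an exposure
#' duration uniform over `exposure_days`. Enrollment is day 0.
#'
#' @param config A [generator_config()].
#' @return A list: `roster` (data frame with id, enrollment/delivery days and
#'   the five demographic columns) and `truth` (data frame with the true
#'   subgroup label per participant).
#' @export
gen_roster <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n
  sspec <- subgroup_spec()
  cls_names <- names(config$subgroup_gamma)
  cls <- sample.int(length(cls_names), n, replace = TRUE,
                    prob = config$subgroup_gamma)
  roster <- data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    enrollment_day = 0L,
    delivery_day = sample(seq(config$exposure_days[1],
                              config$exposure_days[2]), n, replace = TRUE),
    stringsAsFactors = FALSE)
  for (it in sspec$items)
    roster[[it]] <- draw_levels(config$subgroup_rho[[it]], cls,
                                sspec$levels[[it]])
  list(roster = roster,
       truth = data.frame(participant_id = roster$participant_id,
                          subgroup = cls_names[cls],
                          stringsAsFactors = FALSE))
}

#' Generate ground-truth engagement classes and category vectors
#'
#' Draws each participant's engagement-pattern class (marginally, or
#' conditionally on subgroup when the config carries
#' `class_probs_by_subgroup`), then the seven engagement indicators
#' conditionally independently from that class's response rows — exactly the
#' data-generating process a latent class model assumes.
#'
#' @param roster Roster data frame from [gen_roster()].
#' @param config A [generator_config()].
#' @param subgroup Optional character vector of true subgroup labels (needed
#'   only with `class_probs_by_subgroup`).
#' @return Data frame with `participant_id`, `engagement_class`, and the
#'   seven indicator columns (the intended category vector).
#' @export
gen_engagement_categories <- function(roster, config, subgroup = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 1L)
  n <- nrow(roster)
  espec <- engagement_spec()
  cls_names <- names(config$engagement_gamma)
  if (!is.null(config$class_probs_by_subgroup)) {
    if (is.null(subgroup))
      stop2("subgroup labels needed when class probabilities are ",
            "subgroup-conditional")
    sub_idx <- match(subgroup, names(config$subgroup_gamma))
    cls <- vapply(sub_idx, function(s)
      sample.int(length(cls_names), 1L,
                 prob = config$class_probs_by_subgroup[s, ]), integer(1))
  } else {
    cls <- sample.int(length(cls_names), n, replace = TRUE,
                      prob = config$engagement_gamma)
  }
  out <- data.frame(participant_id = roster$participant_id,
                    engagement_class = cls_names[cls],
                    stringsAsFactors = FALSE)
  for (it in espec$items)
    out[[it]] <- draw_levels(config$engagement_rho[[it]], cls,
                             espec$levels[[it]])
  out
}

# windows (by index into scheme) that must receive >= 1 event so that
# categorize_consistency reproduces `category`; NULL when no events.
# Returns list(windows, realized): realized may differ from the intended
# category when it is not renderable at this window count.
consistency_plan <- function(category, scheme) {
  w <- scheme$n_completed
  completed <- seq_len(w)
  partial_idx <- if (scheme$has_partial) scheme$n_windows else NULL
  if (category == "never")
    return(list(windows = integer(0), realized = "never"))
  if (w == 0L)  # lone partial window is the denominator: any event hits it
    return(list(windows = 1L, realized = "consistent"))
  if (category == "consistent")
    return(list(windows = completed, realized = "consistent"))
  if (category == "almost_consistent") {
    if (w >= 2L) {
      k <- ceiling(w / 2)
      return(list(windows = sort(sample(completed, k)),
                  realized = "almost_consistent"))
    }
    # one completed window: any event there means "consistent"
    return(list(windows = completed, realized = "consistent"))
  }
  # inconsistent: need a hit fraction strictly below 0.5 but >= 1 event
  m <- max(1L, ceiling(w / 2) - 1L)
  if (m / w < 0.5)
    return(list(windows = sort(sample(completed, m)),
                realized = "inconsistent"))
  if (!is.null(partial_idx))  # events only in the trailing partial window
    return(list(windows = partial_idx, realized = "inconsistent"))
  # w <= 2 and no partial window: the closest attainable category
  list(windows = if (w == 1L) completed else sample(completed, 1L),
       realized = if (w == 1L) "consistent" else "almost_consistent")
}

#' Render an event log consistent with a category vector
#'
#' The inverse of the engagement categorization: emits timestamped events
#' such that [build_profiles()] applied with the same reference medians
#' reproduces the category vector. Consistency categories place one event in
#' each required window (days uniform within the window); quantity
#' categories draw a total count at/above (`high`) or below (`low`) the
#' reference median, with days uniform over the exposure. Categories that
#' are not attainable at the participant's window count (e.g.
#' `almost_consistent` with a single completed window, or `low` when the
#' reference median is 1) are degraded to the nearest attainable category,
#' which is reported back as the realized category.
#'
#' @param categories Named character vector over the seven engagement
#'   indicators (one participant's category vector).
#' @param scheme The participant's [build_interval_scheme()].
#' @param reference_medians Named positive medians for the quantity features.
#' @param seed Integer seed.
#' @return A list: `events` (data frame `feature`, `day`) and `realized`
#'   (named character vector; equals `categories` wherever renderable).
#' @export
render_events <- function(categories, scheme, reference_medians, seed = 1L) {
  stopifnot(inherits(scheme, "interval_scheme"))
  set.seed(seed)
  feats <- engagement_features()
  missing_f <- setdiff(feats, names(categories))
  if (length(missing_f))
    stop2("categories missing features: ", paste(missing_f, collapse = ", "))
  realized <- categories[feats]
  out_feature <- character(0)
  out_day <- integer(0)

  day_in_window <- function(idx) {
    lo <- scheme$starts[idx]
    hi <- scheme$ends[idx] - 1L
    lo + sample.int(hi - lo + 1L, 1L) - 1L
  }

  for (feat in consistency_features()) {
    plan <- consistency_plan(categories[[feat]], scheme)
    realized[feat] <- plan$realized
    if (length(plan$windows)) {
      days <- vapply(plan$windows, day_in_window, integer(1))
      out_feature <- c(out_feature, rep(feat, length(days)))
      out_day <- c(out_day, days)
    }
  }

  exposure_days <- seq(scheme$enrollment_day, scheme$delivery_day)
  for (feat in quantity_features()) {
    cat_f <- categories[[feat]]
    m <- reference_medians[[feat]]
    count <- 0L
    if (cat_f == "high") {
      count <- as.integer(ceiling(m)) + sample.int(3L, 1L) - 1L
    } else if (cat_f == "low") {
      upper <- if (m == floor(m)) as.integer(m) - 1L else as.integer(floor(m))
      if (upper < 1L) {        # low unattainable when the median is <= 1
        realized[feat] <- "never"
        count <- 0L
      } else {
        count <- sample.int(upper, 1L)
      }
    }
    if (count > 0L) {
      out_feature <- c(out_feature, rep(feat, count))
      out_day <- c(out_day, sample(exposure_days, count, replace = TRUE))
    }
  }

  list(events = data.frame(feature = out_feature, day = as.integer(out_day),
                           stringsAsFactors = FALSE),
       realized = realized)
}

#' Generate a complete synthetic data bundle
#'
#' Composes [gen_roster()], [gen_engagement_categories()] and
#' [render_events()] into the three flat files the analysis pipeline
#' consumes: a roster, a timestamped event log, and a ground-truth table
#' (never fed to the analysis stages) carrying each participant's true
#' subgroup, engagement class, intended category vector and the realized
#' category vector actually encoded in the events.
#'
#' @param config A [generator_config()].
#' @param out_dir Optional directory; when given, writes `roster.csv`,
#'   `events.csv`, `truth.csv` and `medians.json` there.
#' @return A list: `roster`, `events`, `truth` (data frames) and `medians`.
#' @export
gen_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  ros <- gen_roster(config)
  cats <- gen_engagement_categories(ros$roster, config, ros$truth$subgroup)
  feats <- engagement_spec()$items
  n <- nrow(ros$roster)
  ev_list <- vector("list", n)
  realized <- matrix(NA_character_, n, length(feats),
                     dimnames = list(NULL, feats))
  for (i in seq_len(n)) {
    scheme <- build_interval_scheme(ros$roster$enrollment_day[i],
                                    ros$roster$delivery_day[i])
    cat_i <- stats::setNames(unlist(cats[i, feats]), feats)
    rend <- render_events(cat_i, scheme, config$reference_medians,
                          seed = config$seed + 2L + i)
    realized[i, ] <- rend$realized[feats]
    if (nrow(rend$events))
      ev_list[[i]] <- cbind(participant_id = ros$roster$participant_id[i],
                            rend$events)
  }
  keep <- !vapply(ev_list, is.null, logical(1))
  events <- if (any(keep)) do.call(rbind, ev_list[keep]) else
    data.frame(participant_id = character(0), feature = character(0),
               day = integer(0), stringsAsFactors = FALSE)
  rownames(events) <- NULL
  truth <- data.frame(participant_id = ros$roster$participant_id,
                      subgroup = ros$truth$subgroup,
                      engagement_class = cats$engagement_class,
                      cats[feats],
                      stats::setNames(as.data.frame(realized),
                                      paste0("realized_", feats)),
                      stringsAsFactors = FALSE)
  out <- list(roster = ros$roster, events = events, truth = truth,
              medians = config$reference_medians)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$roster, file.path(out_dir, "roster.csv"),
                     row.names = FALSE)
    utils::write.csv(out$events, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    utils::write.csv(out$truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.list(out$medians),
                         file.path(out_dir, "medians.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
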