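#' Declare the categorical indicators of a latent class model
#'
#' An indicator specification names the items entering a latent class
#' analysis and, for each item, its ordered category labels. Every value in a
#' data set passed to the LCA functions must be one of the declared levels.
#'
#' @param levels Named list; one character vector of category labels per item,
#'   each of length >= 2. Item order is taken from the list order.
#' @return An object of class `indicator_spec` with elements `items`
#'   (character vector) and `levels` (named list).
#' @examples
#' indicator_spec(list(smoker = c("yes", "no"),
#'                     bmi    = c("normal", "overweight", "obese")))
#' @export
indicator_spec <- function(levels) {
  if (!is.list(levels) || is.null(names(levels)) || any(names(levels) == ""))
    stop2("`levels` must be a named list of character vectors")
  items <- names(levels)
  if (anyDuplicated(items))
    stop2("item names must be unique")
  for (it in items) {
    lv <- levels[[it]]
    if (!is.character(lv) || length(lv) < 2L || anyDuplicated(lv))
      stop2("item '", it, "' needs >= 2 distinct character levels")
  }
  structure(list(items = items, levels = levels), class = "indicator_spec")
}

#' @export
print.indicator_spec <- function(x, ...) {
  cat("Indicator spec:", length(x$items), "items\n")
  for (it in x$items)
    cat(" ", it, ": ", paste(x$levels[[it]], collapse = " / "), "\n", sep = "")
  invisible(x)
}

# number of levels per item
spec_nlevels <- function(spec) vapply(spec$levels, length, integer(1))

# convert a data.frame of indicator columns to an integer level-code matrix,
# validating against the spec
spec_encode <- function(data, spec) {
  missing_cols <- setdiff(spec$items, names(data))
  if (length(missing_cols))
    stop2("data is missing indicator columns: ",
          paste(missing_cols, collapse = ", "))
  codes <- matrix(NA_integer_, nrow = nrow(data), ncol = length(spec$items),
                  dimnames = list(NULL, spec$items))
  for (j in seq_along(spec$items)) {
    it <- spec$items[j]
    v <- as.character(data[[it]])
    m <- match(v, spec$levels[[it]])
    if (anyNA(m))
      stop2("item '", it, "' contains undeclared levels: ",
            paste(unique(v[is.na(m)]), collapse = ", "))
    codes[, j] <- m
  }
  codes
}

#' Indicator specification for the seven engagement indicators
#'
#' Two consistency-coded items (log-in and weight-tracker use across 45-day
#' intervals) and five quantity-coded "as needed" features.
#'
#' @return An [indicator_spec()].
#' @export
engagement_spec <- function() {
  consistency <- c("consistent", "almost_consistent", "inconsistent", "never")
  quantity <- c("high", "low", "never")
  indicator_spec(list(
    login          = consistency,
    weight_tracker = consistency,
    health_info    = quantity,
    blogs          = quantity,
    resources      = quantity,
    pa_goal        = quantity,
    diet_goal      = quantity
  ))
}

#' Indicator specification for the five demographic/BMI indicators
#'
#' Race, Hispanic ethnicity, low-income status, BMI category and age category,
#' as used to define person-centered demographic/BMI subgroups.
#'
#' @return An [indicator_spec()].
#' @export
subgroup_spec <- function() {
  indicator_spec(list(
    race      = c("white", "black", "other"),
    ethnicity = c("hispanic", "non_hispanic"),
    low_income = c("yes", "no"),
    bmi_cat   = c("normal", "overweight", "obese"),
    age_cat   = c("18_24", "25_29", "30_plus")
  ))
}
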