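# Instrument dialects: the ordered frequency categories offered to a
# respondent and their servings-per-day equivalents.

#' Construct an instrument dialect
#'
#' A dialect is the response vocabulary of one instrument version: an
#' ordered set of frequency category labels and the daily-servings value
#' each maps to. Servings must be non-negative, at most 2 (the "more than
#' once per day" ceiling), and monotone non-decreasing in reported
#' frequency.
#'
#' @param name Dialect name, e.g. `"child"` or `"adult"`.
#' @param categories Ordered character vector of response labels, least to
#'   most frequent.
#' @param servings_per_day Numeric vector of the same length mapping each
#'   label to servings/day.
#' @return An object of class `instrument_dialect`.
#' @export
instrument_dialect <- function(name, categories, servings_per_day) {
  stopifnot(is.character(name), length(name) == 1)
  if (length(categories) != length(servings_per_day)) {
    stop("categories and servings_per_day must have equal length",
         call. = FALSE)
  }
  if (anyDuplicated(categories)) {
    stop("duplicate category labels in dialect '", name, "'", call. = FALSE)
  }
  if (any(servings_per_day < 0) || max(servings_per_day) > 2) {
    stop("servings_per_day must lie in [0, 2]", call. = FALSE)
  }
  if (is.unsorted(servings_per_day)) {
    stop("servings_per_day must be monotone in reported frequency",
         call. = FALSE)
  }
  structure(
    list(
      name = name,
      categories = as.character(categories),
      servings_per_day = stats::setNames(as.numeric(servings_per_day),
                                         categories)
    ),
    class = "instrument_dialect"
  )
}

#' Child instrument dialect
#'
#' Four scored categories (the interviewer's two-step "every day" probe is
#' collapsed upstream into "once a day" vs "more than once per day").
#' "Sometimes" covers everything between never and once per day and is
#' valued at its midpoint, 0.5 servings/day.
#'
#' @return An `instrument_dialect`.
#' @export
child_dialect <- function() {
  instrument_dialect(
    "child",
    categories = c("never", "sometimes", "once a day",
                   "more than once per day"),
    servings_per_day = c(0, 0.5, 1, 2)
  )
}

#' Adult instrument dialect
#'
#' Five categories. "Sometimes but not weekly" is valued at roughly
#' monthly (1/30 ~ 0.033 servings/day) and "weekly" at 1/7 (~0.143).
#'
#' @return An `instrument_dialect`.
#' @export
adult_dialect <- function() {
  instrument_dialect(
    "adult",
    categories = c("never", "sometimes but not weekly", "weekly",
                   "every day", "more than once per day"),
    servings_per_day = c(0, 0.033, 0.143, 1, 2)
  )
}

#' Default dialect set keyed by respondent role
#'
#' @return Named list with elements `child` and `adult`.
#' @export
default_dialects <- function() {
  list(child = child_dialect(), adult = adult_dialect())
}

#' Convert frequency responses to servings per day
#'
#' @param response Character vector of category labels.
#' @param dialect An `instrument_dialect`.
#' @return Numeric vector of servings/day.
#' @examples
#' frequency_to_servings("never", child_dialect())                  # 0
#' frequency_to_servings("more than once per day", child_dialect()) # 2
#' frequency_to_servings("weekly", adult_dialect())                 # ~1/7
#' @export
frequency_to_servings <- function(response, dialect) {
  stopifnot(inherits(dialect, "instrument_dialect"))
  bad <- setdiff(unique(response), dialect$categories)
  if (length(bad) > 0) {
    stop("unknown response label(s) for dialect '", dialect$name, "': ",
         paste0("'", bad, "'", collapse = ", "), call. = FALSE)
  }
  unname(dialect$servings_per_day[response])
}
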