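# Food registry: the card list behind a picture-sort instrument, mapping
# every food card to a grouping, an AHEI component and exclusion flags.

#' Food groupings of the picture-sort instrument
#'
#' The ten major food groupings the instrument covers. Every registry item
#' must belong to one of these.
#'
#' @return Character vector of length 10.
#' @export
food_groupings <- function() {
  c(
    "breads", "vegetables and salad", "fruits", "beverages",
    "soups or stews", "cereals", "dairy and eggs", "rice, pasta, etc.",
    "meat, chicken, or fish", "desserts and snacks"
  )
}

#' AHEI components representable by the instrument
#'
#' The six Alternative Healthy Eating Index components a frequency-only
#' picture-sort can support: vegetables, fruit, whole grains, nuts/legumes,
#' sugar-sweetened beverages plus fruit juice (reverse scored), and
#' red/processed meat (reverse scored). Items contributing to none of them
#' carry component `"none"`.
#'
#' @return Character vector of length 6 (excluding `"none"`).
#' @export
ahei_components <- function() {
  c(
    "vegetables", "fruit", "whole_grains", "nuts_legumes",
    "ssb_juice", "red_processed_meat"
  )
}

#' Components counting as healthy food groups
#'
#' Fresh and dried fruit, vegetables, whole grains, and nuts/legumes: the
#' four components whose scores sum to the healthy foods score and whose
#' servings sum to the healthy food frequency.
#'
#' @return Character vector of length 4.
#' @export
healthy_components <- function() {
  c("vegetables", "fruit", "whole_grains", "nuts_legumes")
}

#' Packaged default food registry
#'
#' A fixture registry of typical items spanning all ten groupings and all
#' six AHEI components, standing in for an instrument's unpublished card
#' list. It is synthetic in composition (the items are real foods, the
#' card list is ours) and is meant to be overridden with
#' [load_food_registry()] when an actual instrument is scored.
#'
#' Conventions encoded here: potatoes never count toward the vegetable
#' component regardless of preparation; fruit juice counts toward the
#' SSB/juice component, not fruit; fried breads (frybread, tortillas) do
#' not count as whole grains; alcohol items are excluded from total food
#' frequency and from child instruments.
#'
#' @return A tibble with one row per food card and columns `item_id`,
#'   `label`, `grouping`, `ahei_component`, `healthy`, `is_potato`,
#'   `is_fruit_juice`, `is_alcohol`, `is_salad`.
#' @export
default_registry <- function() {
  reg <- tibble::tribble(
    ~item_id,           ~label,                          ~grouping,                ~ahei_component,
    "frybread",         "Frybread",                      "breads",                 "none",
    "tortilla",         "Tortilla",                      "breads",                 "none",
    "wheat_bread",      "Whole wheat bread",             "breads",                 "whole_grains",
    "white_bread",      "White bread",                   "breads",                 "none",
    "squash",           "Squash",                        "vegetables and salad",   "vegetables",
    "carrots",          "Carrots",                       "vegetables and salad",   "vegetables",
    "corn",             "Corn on the cob",               "vegetables and salad",   "vegetables",
    "green_salad",      "Green salad",                   "vegetables and salad",   "vegetables",
    "boiled_potatoes",  "Boiled potatoes",               "vegetables and salad",   "none",
    "apple",            "Apple",                         "fruits",                 "fruit",
    "banana",           "Banana",                        "fruits",                 "fruit",
    "melon",            "Melon",                         "fruits",                 "fruit",
    "dried_peaches",    "Dried peaches",                 "fruits",                 "fruit",
    "soda",             "Soda pop",                      "beverages",              "ssb_juice",
    "fruit_juice",      "Fruit juice",                   "beverages",              "ssb_juice",
    "sweet_tea",        "Sweetened tea",                 "beverages",              "ssb_juice",
    "milk",             "Milk",                          "beverages",              "none",
    "beer",             "Beer",                          "beverages",              "none",
    "mutton_stew",      "Mutton stew",                   "soups or stews",         "none",
    "bean_stew",        "Pinto bean stew",               "soups or stews",         "nuts_legumes",
    "vegetable_soup",   "Vegetable soup",                "soups or stews",         "vegetables",
    "menudo",           "Menudo",                        "soups or stews",         "none",
    "blue_corn_mush",   "Blue corn mush",                "cereals",                "whole_grains",
    "oatmeal",          "Oatmeal",                       "cereals",                "whole_grains",
    "sweet_cereal",     "Sweetened cereal",              "cereals",                "none",
    "cheese",           "Cheese",                        "dairy and eggs",         "none",
    "eggs",             "Eggs",                          "dairy and eggs",         "none",
    "yogurt",           "Yogurt",                        "dairy and eggs",         "none",
    "white_rice",       "White rice",                    "rice, pasta, etc.",      "none",
    "brown_rice",       "Brown rice",                    "rice, pasta, etc.",      "whole_grains",
    "macaroni",         "Macaroni",                      "rice, pasta, etc.",      "none",
    "grilled_chicken",  "Grilled chicken",               "meat, chicken, or fish", "none",
    "mutton",           "Roast mutton",                  "meat, chicken, or fish", "red_processed_meat",
    "spam",             "Canned luncheon meat",          "meat, chicken, or fish", "red_processed_meat",
    "fish",             "Fish",                          "meat, chicken, or fish", "none",
    "cookies",          "Cookies",                       "desserts and snacks",    "none",
    "chips",            "Potato chips",                  "desserts and snacks",    "none",
    "peanuts",          "Peanuts",                       "desserts and snacks",    "nuts_legumes",
    "fruit_cup",        "Fruit cup",                     "desserts and snacks",    "fruit"
  )
  reg$is_potato <- reg$item_id %in% c("boiled_potatoes", "chips")
  reg$is_fruit_juice <- reg$item_id == "fruit_juice"
  reg$is_alcohol <- reg$item_id == "beer"
  reg$is_salad <- reg$item_id == "green_salad"
  validate_registry(reg)
}

registry_flag_cols <- c("is_potato", "is_fruit_juice", "is_alcohol", "is_salad")

#' Validate a food registry
#'
#' Enforces the registry invariants: unique item ids; groupings drawn from
#' [food_groupings()]; AHEI components drawn from [ahei_components()] or
#' `"none"`; potato items never assigned to the vegetable component; fruit
#' juice items assigned to the SSB/juice component; and the `healthy` flag
#' equal to membership of the component in [healthy_components()] (it is
#' derived when absent).
#'
#' @param registry A data frame of food items.
#' @return The validated registry as a tibble, with `healthy` filled in and
#'   flag columns defaulted to `FALSE` where missing.
#' @export
validate_registry <- function(registry) {
  reg <- tibble::as_tibble(registry)
  needed <- c("item_id", "label", "grouping", "ahei_component")
  missing_cols <- setdiff(needed, names(reg))
  if (length(missing_cols) > 0) {
    stop("registry is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (fl in registry_flag_cols) {
    if (!fl %in% names(reg)) reg[[fl]] <- FALSE
    reg[[fl]] <- as.logical(reg[[fl]])
  }
  if (anyDuplicated(reg$item_id)) {
    dup <- unique(reg$item_id[duplicated(reg$item_id)])
    stop("duplicate item_id in registry: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_group <- which(!reg$grouping %in% food_groupings())
  if (length(bad_group) > 0) {
    stop(
      "row ", bad_group[1], " (item '", reg$item_id[bad_group[1]],
      "'): unknown grouping '", reg$grouping[bad_group[1]],
      "'; allowed groupings are: ",
      paste(food_groupings(), collapse = "; "),
      call. = FALSE
    )
  }
  bad_comp <- which(!reg$ahei_component %in% c(ahei_components(), "none"))
  if (length(bad_comp) > 0) {
    stop(
      "row ", bad_comp[1], " (item '", reg$item_id[bad_comp[1]],
      "'): unknown ahei_component '", reg$ahei_component[bad_comp[1]], "'",
      call. = FALSE
    )
  }
  potato_veg <- which(reg$is_potato & reg$ahei_component == "vegetables")
  if (length(potato_veg) > 0) {
    stop(
      "row ", potato_veg[1], " (item '", reg$item_id[potato_veg[1]],
      "'): potato items cannot carry ahei_component 'vegetables'; ",
      "the vegetable component does not include potatoes",
      call. = FALSE
    )
  }
  juice_bad <- which(reg$is_fruit_juice &
                       !reg$ahei_component %in% c("ssb_juice", "none"))
  if (length(juice_bad) > 0) {
    stop(
      "row ", juice_bad[1], " (item '", reg$item_id[juice_bad[1]],
      "'): fruit juice items count toward 'ssb_juice', not '",
      reg$ahei_component[juice_bad[1]], "'",
      call. = FALSE
    )
  }
  derived_healthy <- reg$ahei_component %in% healthy_components()
  if ("healthy" %in% names(reg)) {
    mism <- which(as.logical(reg$healthy) != derived_healthy)
    if (length(mism) > 0) {
      stop(
        "row ", mism[1], " (item '", reg$item_id[mism[1]],
        "'): 'healthy' flag inconsistent with ahei_component; healthy ",
        "items are exactly those in components ",
        paste(healthy_components(), collapse = ", "),
        call. = FALSE
      )
    }
  }
  reg$healthy <- derived_healthy
  reg[, c("item_id", "label", "grouping", "ahei_component", "healthy",
          registry_flag_cols)]
}

#' Read a food registry from JSON or CSV
#'
#' @param path Path to a `.json` file (an array of item objects) or a
#'   `.csv` file with a header row. All registry invariants are enforced;
#'   violations are rejected with the offending row named.
#' @return A validated registry tibble (see [default_registry()]).
#' @export
load_food_registry <- function(path) {
  if (!file.exists(path)) {
    stop("registry file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  reg <- switch(ext,
    json = tibble::as_tibble(jsonlite::fromJSON(path)),
    csv = tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE)),
    stop("unsupported registry format '.", ext, "'; use .json or .csv",
         call. = FALSE)
  )
  validate_registry(reg)
}

#' Write a food registry to JSON or CSV
#'
#' @param registry A registry tibble.
#' @param path Output path ending in `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_food_registry <- function(registry, path) {
  reg <- validate_registry(registry)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(reg, path, auto_unbox = FALSE, digits = NA,
                         pretty = TRUE)
  } else if (ext == "csv") {
    utils::write.csv(reg, path, row.names = FALSE)
  } else {
    stop("unsupported registry format '.", ext, "'; use .json or .csv",
         call. = FALSE)
  }
  invisible(path)
}
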