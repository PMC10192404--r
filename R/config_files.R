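# File-based configuration: component scoring standards and instrument
# dialects can be kept in YAML (or JSON/CSV) rather than code.

read_config_table <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml = tibble::as_tibble(
      do.call(rbind, lapply(yaml::read_yaml(path), as.data.frame))),
    json = tibble::as_tibble(jsonlite::fromJSON(path)),
    csv = tibble::as_tibble(utils::read.csv(path,
                                            stringsAsFactors = FALSE)),
    stop("unsupported config format '.", ext, "'", call. = FALSE)
  )
}

#' Read component scoring standards from a file
#'
#' Accepts YAML (a list of component records), JSON, or CSV with the
#' columns of [default_standards()].
#'
#' @param path Path to the standards file.
#' @return A standards tibble.
#' @export
load_standards <- function(path) {
  std <- read_config_table(path)
  needed <- c("component", "direction", "zero_score_servings",
              "full_score_servings")
  missing_cols <- setdiff(needed, names(std))
  if (length(missing_cols) > 0) {
    stop("standards file is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(std$component, ahei_components())
  if (length(unknown) > 0) {
    stop("unknown component(s) in standards file: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  std[, needed]
}

#' Read instrument dialects from a file
#'
#' Accepts YAML or JSON: a mapping from dialect name to a record with
#' `categories` and `servings_per_day` arrays. All
#' [instrument_dialect()] invariants are enforced.
#'
#' @param path Path to the dialects file.
#' @return Named list of `instrument_dialect`s.
#' @export
load_dialects <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    stop("unsupported dialect format '.", ext, "'", call. = FALSE)
  )
  out <- lapply(names(raw), function(nm) {
    instrument_dialect(nm, unlist(raw[[nm]]$categories),
                       unlist(raw[[nm]]$servings_per_day))
  })
  stats::setNames(out, names(raw))
}
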