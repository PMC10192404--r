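# Long-format picture-sort response tables and their validation.

response_cols <- c("subject_id", "role", "timepoint", "item_id", "response")

#' Validate a long-format response table
#'
#' Checks each record against the registry and the dialect of its role:
#' roles must be names of `dialects`, timepoints must be `baseline` or
#' `followup`, item ids must exist in the registry, response labels must be
#' valid for the role's dialect, and (subject, timepoint, item) must be
#' unique. Child responses to alcohol items are flagged as warnings
#' (alcohol cards are an adult-only part of the instrument).
#'
#' Problems are reported, not thrown, so a whole file can be checked in
#' one pass; downstream scoring refuses tables with a non-empty error set.
#'
#' @param records A data frame with columns
#'   `subject_id, role, timepoint, item_id, response`.
#' @param registry A validated food registry.
#' @param dialects Named list of `instrument_dialect`s keyed by role.
#' @return A list with `records` (tibble) and `report`, itself a list of
#'   `errors` and `warnings` tibbles with columns `row`, `rule`, `message`.
#' @export
validate_responses <- function(records, registry = default_registry(),
                               dialects = default_dialects()) {
  rec <- tibble::as_tibble(records)
  missing_cols <- setdiff(response_cols, names(rec))
  if (length(missing_cols) > 0) {
    stop("response table is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(rec) == 0) {
    stop("response table is empty", call. = FALSE)
  }
  err <- list()
  wrn <- list()
  note <- function(row, rule, message) {
    tibble::tibble(row = row, rule = rule, message = message)
  }

  bad_role <- which(!rec$role %in% names(dialects))
  if (length(bad_role) > 0) {
    err[["role"]] <- note(bad_role, "unknown_role",
                          paste0("unknown role '", rec$role[bad_role], "'"))
  }
  bad_tp <- which(!rec$timepoint %in% c("baseline", "followup"))
  if (length(bad_tp) > 0) {
    err[["timepoint"]] <- note(
      bad_tp, "unknown_timepoint",
      paste0("timepoint must be 'baseline' or 'followup', got '",
             rec$timepoint[bad_tp], "'"))
  }
  bad_item <- which(!rec$item_id %in% registry$item_id)
  if (length(bad_item) > 0) {
    err[["item"]] <- note(
      bad_item, "unknown_item",
      paste0("item_id '", rec$item_id[bad_item], "' not in registry"))
  }
  for (role in intersect(unique(rec$role), names(dialects))) {
    d <- dialects[[role]]
    idx <- which(rec$role == role & !rec$response %in% d$categories)
    if (length(idx) > 0) {
      err[[paste0("label_", role)]] <- note(
        idx, "invalid_response_label",
        paste0("response '", rec$response[idx], "' not valid for the ",
               role, " dialect"))
    }
  }
  key <- paste(rec$subject_id, rec$timepoint, rec$item_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    err[["dup"]] <- note(
      dup, "duplicate_record",
      paste0("duplicate record for (", rec$subject_id[dup], ", ",
             rec$timepoint[dup], ", ", rec$item_id[dup], ")"))
  }
  alc <- registry$item_id[registry$is_alcohol]
  child_alc <- which(rec$role == "child" & rec$item_id %in% alc)
  if (length(child_alc) > 0) {
    wrn[["alc"]] <- note(
      child_alc, "alcohol_item_for_child",
      paste0("alcohol item '", rec$item_id[child_alc],
             "' answered by a child respondent"))
  }

  bind_notes <- function(x) {
    if (length(x) == 0) {
      tibble::tibble(row = integer(), rule = character(),
                     message = character())
    } else {
      dplyr::arrange(dplyr::bind_rows(x), .data$row)
    }
  }
  list(records = rec,
       report = list(errors = bind_notes(err), warnings = bind_notes(wrn)))
}

#' Read a picture-sort response table from CSV
#'
#' The file must carry exactly the header
#' `subject_id,role,timepoint,item_id,response`. Parsing and validation
#' are separated: an unreadable or empty file raises immediately, whereas
#' rule violations are collected in the returned validation report.
#'
#' @inheritParams validate_responses
#' @param path Path to the CSV file.
#' @return As [validate_responses()].
#' @export
load_response_table <- function(path, registry = default_registry(),
                                dialects = default_dialects()) {
  if (!file.exists(path)) {
    stop("response file not found: ", path, call. = FALSE)
  }
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!identical(sort(names(rec)), sort(response_cols))) {
    stop("response file must have header exactly: ",
         paste(response_cols, collapse = ","), call. = FALSE)
  }
  validate_responses(rec[, response_cols], registry, dialects)
}

#' Stop unless a validation report is clean
#'
#' @param validated Output of [validate_responses()].
#' @return The `records` tibble, invisibly usable downstream.
#' @export
assert_valid_responses <- function(validated) {
  errs <- validated$report$errors
  if (nrow(errs) > 0) {
    stop("response table failed validation (", nrow(errs), " error(s)); ",
         "first: row ", errs$row[1], ": ", errs$message[1], call. = FALSE)
  }
  validated$records
}
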