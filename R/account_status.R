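#' Default account-status vocabulary
#'
#' Status categories of the account-status history, in reporting order.
#' Category encodings vary by site, so this is configuration.
#'
#' @return Character vector.
#' @export
default_status_levels <- function() {
  c("Activated", "Inactivated", "Patient declined", "Pending activation")
}

#' Read an account-status history export
#'
#' Reads the five status-history columns (`PAT_MRN_ID`, `MYC_STATUS_HX`,
#' `MYC_STATUS_TMSTP`, `MYC_STATUS_MTHD`, `MYC_STATUS_CMT`) from a
#' delimited file. Unknown status values are flagged with a warning, not
#' dropped.
#'
#' @param path Path to the delimited file.
#' @param delim Field delimiter.
#' @param status_levels Known status vocabulary.
#' @param timestamp_format `strptime` format of `MYC_STATUS_TMSTP`.
#' @return Tibble with `patient_id`, `status`, `timestamp`, `method`,
#'   `comment`.
#' @export
read_status_history <- function(path, delim = "\t",
                                status_levels = default_status_levels(),
                                timestamp_format = "%Y-%m-%d %H:%M:%S") {
  if (!file.exists(path)) {
    stop("status history file does not exist: ", path, call. = FALSE)
  }
  raw <- readr::read_delim(
    path, delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    trim_ws = FALSE, na = character(), progress = FALSE,
    show_col_types = FALSE)
  need <- c("PAT_MRN_ID", "MYC_STATUS_HX", "MYC_STATUS_TMSTP",
            "MYC_STATUS_MTHD", "MYC_STATUS_CMT")
  idx <- match(tolower(need), tolower(names(raw)))
  if (anyNA(idx)) {
    stop("status history is missing required column(s): ",
         paste(need[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    patient_id = trimws(raw[[idx[1]]]),
    status = trimws(raw[[idx[2]]]),
    timestamp = parse_ua_time(raw[[idx[3]]], timestamp_format),
    method = normalize_text(raw[[idx[4]]]),
    comment = normalize_text(raw[[idx[5]]])
  )
  unknown <- setdiff(unique(out$status), status_levels)
  if (length(unknown)) {
    warning("unknown account status value(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  out
}

#' Summarize one patient's account-status history
#'
#' Activation time is the earliest `Activated` event (absent if none);
#' current status is the latest event's status (timestamp ties broken by
#' last in input order); `deceased` is true when any `Inactivated` event's
#' comment matches the configured pattern — most inactivated accounts at
#' the reference site were closed on the owner's death.
#'
#' @param events Tibble of one patient's status events (`status`,
#'   `timestamp`, `comment`).
#' @param deceased_pattern Regular expression matched (case-insensitively)
#'   against comments of `Inactivated` events.
#' @return One-row tibble (`activation_time`, `current_status`,
#'   `deceased`), or `NULL` for an empty history (patient never
#'   registered).
#' @export
summarize_account <- function(events, deceased_pattern = "deceased") {
  if (is.null(events) || nrow(events) == 0L) return(NULL)
  ord <- order(events$timestamp, seq_len(nrow(events)), method = "radix")
  ev <- events[ord, , drop = FALSE]
  act <- ev$timestamp[ev$status == "Activated"]
  dec <- ev$status == "Inactivated" & !is.na(ev$comment) &
    grepl(deceased_pattern, ev$comment, ignore.case = TRUE)
  tibble::tibble(
    activation_time = if (length(act)) min(act) else
      as.POSIXct(NA, tz = "UTC"),
    current_status = ev$status[nrow(ev)],
    deceased = any(dec)
  )
}

#' Summarize all patients' account-status histories
#'
#' Vectorized wrapper over [summarize_account()]: one row per patient with
#' at least one status event.
#'
#' @param events Tibble from [read_status_history()] (multiple patients).
#' @param deceased_pattern See [summarize_account()].
#' @return Tibble with `patient_id`, `activation_time`, `current_status`,
#'   `deceased`.
#' @export
summarize_accounts <- function(events, deceased_pattern = "deceased") {
  if (nrow(events) == 0L) {
    return(tibble::tibble(patient_id = character(),
                          activation_time = as.POSIXct(character(), tz = "UTC"),
                          current_status = character(),
                          deceased = logical()))
  }
  events %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::group_modify(~ summarize_account(.x, deceased_pattern)) %>%
    dplyr::ungroup()
}

#' Account-status frequency table
#'
#' Counts and percentages of current account status across patients, in
#' the configured category order; statuses outside the vocabulary are
#' appended at the end.
#'
#' @param summaries Tibble from [summarize_accounts()].
#' @param status_levels Reporting order.
#' @return Tibble with `status`, `n`, `percent` (percentages sum to 100 up
#'   to rounding); zero rows for empty input.
#' @export
status_table <- function(summaries, status_levels = default_status_levels()) {
  if (nrow(summaries) == 0L) {
    return(tibble::tibble(status = character(), n = integer(),
                          percent = numeric()))
  }
  lv <- c(status_levels, setdiff(unique(summaries$current_status),
                                 status_levels))
  n <- vapply(lv, function(s) sum(summaries$current_status == s), integer(1))
  out <- tibble::tibble(status = lv, n = unname(n),
                        percent = 100 * unname(n) / nrow(summaries))
  out[out$n > 0 | out$status %in% status_levels, , drop = FALSE]
}
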