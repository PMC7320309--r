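#' Partition an audit log into sessions
#'
#' Groups each patient's records into coherent sessions, superseding the
#' server-assigned `UA_SESSION_NUM` (which may be untracked, intermittent,
#' or span multiple days). A new session starts at:
#' \itemize{
#'   \item a patient's first record;
#'   \item any log-in record (an explicit re-login is a new engagement);
#'   \item any record whose gap from the previous record is strictly
#'     greater than `threshold_seconds`;
#'   \item the first record after a log-out.
#' }
#' A gap exactly equal to the threshold does not split. Session identifiers
#' are deterministic: `<patient_id>-S<index>` in canonical order.
#'
#' @param log A canonically sorted `audit_log`.
#' @param threshold_seconds Positive inactivity threshold (seconds); see
#'   [estimate_threshold()] and [default_threshold_seconds()].
#' @param login_labels,logout_labels Miscellaneous-action flags used for the
#'   boundary rules (case-insensitive).
#' @return A `session_log`: the record tibble with a `session_id` column
#'   appended. The partition is total — every record belongs to exactly one
#'   session.
#' @export
assign_sessions <- function(log, threshold_seconds = default_threshold_seconds(),
                            login_labels = "Login", logout_labels = "Logout") {
  stopifnot(inherits(log, "audit_log"))
  if (!is.numeric(threshold_seconds) || length(threshold_seconds) != 1L ||
      threshold_seconds <= 0) {
    stop("threshold_seconds must be a single positive number", call. = FALSE)
  }
  if (!isTRUE(attr(log, "sorted"))) {
    stop("assign_sessions() requires a canonically sorted log", call. = FALSE)
  }
  n <- nrow(log)
  out <- tibble::as_tibble(log)
  if (n == 0L) {
    out$session_id <- character()
    return(structure(out, class = c("session_log", class(tibble::tibble())),
                     threshold_seconds = threshold_seconds))
  }
  a <- tolower(log$action_type)
  is_login <- a %in% tolower(login_labels)
  is_logout <- a %in% tolower(logout_labels)
  new_patient <- c(TRUE, log$patient_id[-1L] != log$patient_id[-n])
  gap <- c(NA_real_, diff(as.numeric(log$timestamp)))
  after_logout <- c(FALSE, is_logout[-n])
  starts <- new_patient | is_login |
    (!new_patient & gap > threshold_seconds) |
    (!new_patient & after_logout)
  starts[is.na(starts)] <- TRUE
  sess_index <- stats::ave(as.integer(starts), log$patient_id,
                           FUN = cumsum)
  out$session_id <- sprintf("%s-S%d", log$patient_id, sess_index)
  structure(out, class = c("session_log", class(tibble::tibble())),
            threshold_seconds = threshold_seconds)
}

#' Infer the device type used in a session
#'
#' Mobile if any record's user agent or extended info contains a configured
#' mobile marker (the Epic mobile client identifies itself with
#' `"EpicMyChart"`); desktop if a log-in record carries a non-missing agent
#' without mobile markers; unknown otherwise.
#'
#' @param records Tibble of one session's records (`action_type`,
#'   `user_agent`, `extended_info`).
#' @param mobile_markers Substrings marking a mobile client
#'   (case-insensitive); institutions differ, so this is configuration.
#' @param login_labels Log-in action types.
#' @return One of `"mobile"`, `"desktop"`, `"unknown"`.
#' @export
infer_device <- function(records, mobile_markers = "EpicMyChart",
                         login_labels = "Login") {
  evidence <- c(records$user_agent, records$extended_info)
  evidence <- evidence[!is.na(evidence)]
  pat <- paste0(vapply(mobile_markers, function(m)
    paste0("\\Q", m, "\\E"), character(1)), collapse = "|")
  if (length(evidence) && any(grepl(pat, evidence, ignore.case = TRUE,
                                    perl = TRUE))) {
    return("mobile")
  }
  logins <- tolower(records$action_type) %in% tolower(login_labels)
  if (any(logins & !is.na(records$user_agent))) return("desktop")
  "unknown"
}

#' Effective time in session
#'
#' Seconds between the first and last non-log-out records of a session;
#' 0 when fewer than two such records exist. Log-outs are excluded because
#' server keep-alive log-outs, stamped around 20 minutes after the last
#' real action, consistently overestimate engagement. Durations are
#' computed before duplicate removal — duplicates inflate counts, not time.
#'
#' @param records Tibble of one session's records in canonical order.
#' @param logout_labels Log-out action types.
#' @return Duration in whole seconds (non-negative integer).
#' @export
session_duration <- function(records, logout_labels = "Logout") {
  keep <- !(tolower(records$action_type) %in% tolower(logout_labels))
  ts <- records$timestamp[keep]
  if (length(ts) < 2L) return(0L)
  as.integer(max(as.numeric(ts)) - min(as.numeric(ts)))
}

#' Session-level attributes of a sessionized log
#'
#' One row per session with start time, inferred device, effective
#' duration, and action count. Call this before [dedup_actions()] so that
#' durations reflect the raw record stream.
#'
#' @param slog A `session_log` from [assign_sessions()].
#' @param mobile_markers,login_labels,logout_labels See [infer_device()]
#'   and [session_duration()].
#' @return Tibble with `session_id`, `patient_id`, `start_time`, `device`,
#'   `duration_seconds`, `n_actions`, `server_sessions` (distinct
#'   `UA_SESSION_NUM` values, diagnostics only).
#' @export
session_table <- function(slog, mobile_markers = "EpicMyChart",
                          login_labels = "Login", logout_labels = "Logout") {
  stopifnot(inherits(slog, "session_log"))
  if (nrow(slog) == 0L) {
    return(tibble::tibble(session_id = character(), patient_id = character(),
                          start_time = as.POSIXct(character(), tz = "UTC"),
                          device = character(), duration_seconds = integer(),
                          n_actions = integer(), server_sessions = integer()))
  }
  slog %>%
    dplyr::group_by(.data$session_id, .data$patient_id) %>%
    dplyr::summarise(
      start_time = min(.data$timestamp),
      device = infer_device(dplyr::pick(dplyr::everything()),
                            mobile_markers = mobile_markers,
                            login_labels = login_labels),
      duration_seconds = session_duration(dplyr::pick(dplyr::everything()),
                                          logout_labels = logout_labels),
      n_actions = dplyr::n(),
      server_sessions = dplyr::n_distinct(.data$server_session, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$patient_id, .data$start_time, .data$session_id)
}
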