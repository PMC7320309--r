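#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

#' Canonical audit-log column names and accepted aliases
#'
#' The six user-access columns exported from the Clarity `MYC_PT_USER_ACCSS`
#' table. Printed excerpts sometimes abbreviate `PAT_MRN_ID` as `PT_MRN_ID`;
#' both are accepted. Matching is case-insensitive.
#'
#' @return Named list mapping canonical names to character vectors of
#'   accepted header spellings.
#' @export
default_column_aliases <- function() {
  list(
    patient_id     = c("PAT_MRN_ID", "PT_MRN_ID"),
    timestamp      = c("UA_TIME"),
    action_type    = c("MYC_UA_TYPE_C"),
    extended_info  = c("UA_EXTENDED_INFO"),
    server_session = c("UA_SESSION_NUM"),
    user_agent     = c("UA_USER_AGENT")
  )
}

# Free text comes out of Clarity with padding and the literal string "Null"
# standing in for missing values.
normalize_text <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x) | tolower(x) == "null"] <- NA_character_
  x
}

parse_ua_time <- function(x, format = "%Y-%m-%d %H:%M:%S") {
  # Timezone-naive: UA_TIME carries no zone, so a fixed zone keeps
  # subtraction purely arithmetic (no DST jumps).
  as.POSIXct(trimws(as.character(x)), format = format, tz = "UTC")
}

#' Read a raw portal audit-log export
#'
#' Reads a delimited text export of the user-access audit table, normalizes
#' free-text fields (trimming, `"Null"`/empty to `NA`), parses `UA_TIME`
#' at one-second resolution, and returns an `audit_log` tibble. Rows whose
#' timestamp does not parse are rejected into a report attached to the
#' result (see [ingest_report()]); they are never silently dropped.
#'
#' @param path Path to the delimited file.
#' @param delim Field delimiter (default tab).
#' @param col_aliases Header-alias table, see [default_column_aliases()].
#' @param timestamp_format `strptime` format of `UA_TIME`
#'   (default `"%Y-%m-%d %H:%M:%S"`).
#' @return A tibble of class `audit_log` with columns `patient_id`,
#'   `timestamp`, `action_type`, `extended_info`, `server_session`,
#'   `user_agent`, `.row` (stable input index). Attributes: `provenance`
#'   (source path and options) and `rejects` (tibble of rejected rows).
#' @export
read_audit_log <- function(path, delim = "\t",
                           col_aliases = default_column_aliases(),
                           timestamp_format = "%Y-%m-%d %H:%M:%S") {
  if (!file.exists(path)) {
    stop("audit log file does not exist: ", path, call. = FALSE)
  }
  if (file.size(path) == 0) {
    return(new_audit_log(
      tibble::tibble(patient_id = character(),
                     timestamp = as.POSIXct(character(), tz = "UTC"),
                     action_type = character(), extended_info = character(),
                     server_session = character(), user_agent = character(),
                     .row = integer()),
      provenance = list(path = path, delim = delim,
                        timestamp_format = timestamp_format,
                        n_rows_read = 0L)))
  }
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    trim_ws = FALSE, na = character(), progress = FALSE,
    show_col_types = FALSE
  )
  header <- names(raw)
  idx <- vapply(col_aliases, function(aliases) {
    hit <- which(tolower(header) %in% tolower(aliases))
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }, integer(1))
  if (anyNA(idx)) {
    missing_cols <- vapply(col_aliases[is.na(idx)], `[`, character(1), 1L)
    stop("audit log is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  log <- tibble::tibble(
    patient_id     = trimws(raw[[idx[["patient_id"]]]]),
    timestamp      = parse_ua_time(raw[[idx[["timestamp"]]]], timestamp_format),
    action_type    = trimws(raw[[idx[["action_type"]]]]),
    extended_info  = normalize_text(raw[[idx[["extended_info"]]]]),
    server_session = normalize_text(raw[[idx[["server_session"]]]]),
    user_agent     = normalize_text(raw[[idx[["user_agent"]]]]),
    .row           = seq_len(nrow(raw))
  )

  bad <- which(is.na(log$timestamp))
  rejects <- tibble::tibble(
    row = bad,
    raw_timestamp = if (length(bad)) trimws(raw[[idx[["timestamp"]]]][bad]) else character(),
    reason = rep("unparseable timestamp", length(bad))
  )
  if (length(bad)) {
    warning(length(bad), " row(s) rejected for unparseable timestamps; ",
            "see ingest_report()", call. = FALSE)
    log <- log[-bad, , drop = FALSE]
  }

  new_audit_log(log,
                provenance = list(path = path, delim = delim,
                                  timestamp_format = timestamp_format,
                                  n_rows_read = nrow(raw)),
                rejects = rejects)
}

new_audit_log <- function(df, provenance = list(), rejects = NULL,
                          sorted = FALSE) {
  df <- tibble::as_tibble(df)
  if (is.null(rejects)) {
    rejects <- tibble::tibble(row = integer(), raw_timestamp = character(),
                              reason = character())
  }
  structure(df,
            class = c("audit_log", class(tibble::tibble())),
            provenance = provenance, rejects = rejects, sorted = sorted)
}

#' Ingest report for an audit log
#'
#' @param log An `audit_log`.
#' @return List with `n_records`, `n_rejected`, `rejects` (tibble with row
#'   numbers and reasons), and `provenance`.
#' @export
ingest_report <- function(log) {
  stopifnot(inherits(log, "audit_log"))
  rejects <- attr(log, "rejects")
  list(
    n_records = nrow(log),
    n_rejected = nrow(rejects),
    rejects = rejects,
    provenance = attr(log, "provenance")
  )
}

#' @export
print.audit_log <- function(x, ...) {
  cat(sprintf("<audit_log> %d records, %d patient(s)%s\n",
              nrow(x), dplyr::n_distinct(x$patient_id),
              if (isTRUE(attr(x, "sorted"))) ", canonically sorted" else ""))
  NextMethod()
}

tie_rank <- function(action_type, login_labels, logout_labels) {
  a <- tolower(trimws(action_type))
  rank <- rep(1L, length(a))
  rank[a %in% tolower(login_labels)] <- 0L
  rank[a %in% tolower(logout_labels)] <- 2L
  rank
}

#' Canonically order an audit log
#'
#' Orders records by patient, then timestamp; among records sharing one
#' timestamp, log-ins come first (so a log-in opens its second), log-outs
#' last, and remaining ties keep stable input order. The result is
#' deterministic for any input permutation of the same rows, which makes
#' downstream sessionization reproducible.
#'
#' @param log An `audit_log`.
#' @param login_labels,logout_labels Action-type strings treated as log-in /
#'   log-out (case-insensitive). Defaults `"Login"` / `"Logout"`.
#' @return The sorted `audit_log` (attribute `sorted = TRUE`).
#' @export
canonical_sort <- function(log, login_labels = "Login",
                           logout_labels = "Logout") {
  stopifnot(inherits(log, "audit_log"))
  rk <- tie_rank(log$action_type, login_labels, logout_labels)
  ord <- order(log$patient_id, log$timestamp, rk, log$.row, method = "radix")
  out <- log[ord, , drop = FALSE]
  out$.row <- seq_len(nrow(out))
  new_audit_log(out, provenance = attr(log, "provenance"),
                rejects = attr(log, "rejects"), sorted = TRUE)
}

#' Write an audit log back to delimited text
#'
#' Emits the six Clarity-named columns in Table-2 order with `NA` rendered
#' as `"Null"`, so a written log re-reads to the same record multiset.
#'
#' @param log An `audit_log`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_audit_log <- function(log, path, delim = "\t") {
  stopifnot(inherits(log, "audit_log"))
  out <- tibble::tibble(
    PAT_MRN_ID = log$patient_id,
    UA_TIME = format(log$timestamp, "%Y-%m-%d %H:%M:%S"),
    MYC_UA_TYPE_C = log$action_type,
    UA_EXTENDED_INFO = ifelse(is.na(log$extended_info), "Null", log$extended_info),
    UA_SESSION_NUM = ifelse(is.na(log$server_session), "Null", log$server_session),
    UA_USER_AGENT = ifelse(is.na(log$user_agent), "Null", log$user_agent)
  )
  readr::write_delim(out, path, delim = delim, na = "Null", progress = FALSE)
  invisible(path)
}

#' Build an audit log from an in-memory data frame
#'
#' Convenience constructor used by the simulator and tests: applies the same
#' normalization as [read_audit_log()] to a data frame already carrying the
#' canonical column names.
#'
#' @param df Data frame with columns `patient_id`, `timestamp` (POSIXct or
#'   `"%Y-%m-%d %H:%M:%S"` strings), `action_type`, and optionally
#'   `extended_info`, `server_session`, `user_agent`.
#' @return An `audit_log`.
#' @export
as_audit_log <- function(df) {
  ts <- df$timestamp
  if (!inherits(ts, "POSIXct")) ts <- parse_ua_time(ts)
  if (anyNA(ts)) stop("unparseable timestamp in as_audit_log()", call. = FALSE)
  opt <- function(col) {
    if (col %in% names(df)) normalize_text(df[[col]]) else
      rep(NA_character_, nrow(df))
  }
  new_audit_log(tibble::tibble(
    patient_id = trimws(as.character(df$patient_id)),
    timestamp = ts,
    action_type = trimws(as.character(df$action_type)),
    extended_info = opt("extended_info"),
    server_session = opt("server_session"),
    user_agent = opt("user_agent"),
    .row = seq_len(nrow(df))
  ), provenance = list(path = NA_character_))
}
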