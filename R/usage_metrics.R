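#' Remove consecutive duplicate actions within sessions
#'
#' The mobile client can re-log the same user action every ~2 seconds while
#' a page stays open, inflating frequency counts (but not durations, which
#' are computed before this step). Within each session, consecutive runs of
#' records with identical `action_type` and `extended_info` collapse to
#' their first record; non-consecutive repeats survive.
#'
#' @param slog A `session_log` in canonical order.
#' @param max_interval Optional cap in seconds: a repeat further than this
#'   from its predecessor is kept even if identical (default `Inf`, i.e.
#'   value matching alone decides, the reference behaviour).
#' @return The deduplicated `session_log`; idempotent.
#' @export
dedup_actions <- function(slog, max_interval = Inf) {
  stopifnot(inherits(slog, "session_log"))
  n <- nrow(slog)
  if (n <= 1L) return(slog)
  same <- c(FALSE,
            slog$session_id[-1L] == slog$session_id[-n] &
            slog$action_type[-1L] == slog$action_type[-n] &
            (slog$extended_info[-1L] == slog$extended_info[-n] |
               (is.na(slog$extended_info[-1L]) & is.na(slog$extended_info[-n]))))
  same[is.na(same)] <- FALSE
  if (is.finite(max_interval)) {
    gap <- c(Inf, diff(as.numeric(slog$timestamp)))
    same <- same & gap <= max_interval
  }
  out <- slog[!same, , drop = FALSE]
  attributes(out)$threshold_seconds <- attr(slog, "threshold_seconds")
  out
}

#' Per-session usage metrics
#'
#' Frequency counts per portal function and comprehensiveness (number of
#' distinct functions used) for each session. Counts cover classified,
#' non-Miscellaneous records only; Unclassified records are excluded from
#' counts and comprehensiveness but reported in `n_unclassified`. A session
#' is valid iff its effective duration is nonzero — log-in attempts that
#' led nowhere are flagged invalid.
#'
#' @param slog A deduplicated, categorized `session_log` (see
#'   [dedup_actions()], [categorize()]).
#' @param session_info Session attributes from [session_table()], computed
#'   on the pre-dedup log so durations are unaffected by duplicate removal.
#' @return Tibble with one row per session: `session_id`, `patient_id`,
#'   `start_time`, `device`, `duration_seconds`, one count column per
#'   portal function (backtick-quoted where names contain spaces),
#'   `n_unclassified`, `comprehensiveness` (0-8), `is_valid`.
#' @export
session_metrics <- function(slog, session_info) {
  stopifnot(inherits(slog, "session_log"))
  if (!"portal_function" %in% names(slog)) {
    stop("records are not categorized; call categorize() first", call. = FALSE)
  }
  fns <- portal_functions()

  counts <- slog %>%
    dplyr::filter(!.data$portal_function %in% c("Miscellaneous", "Unclassified")) %>%
    dplyr::count(.data$session_id, .data$portal_function) %>%
    tidyr::pivot_wider(names_from = "portal_function", values_from = "n",
                       values_fill = 0L)
  for (fn in setdiff(fns, names(counts))) counts[[fn]] <- 0L

  uncl <- slog %>%
    dplyr::group_by(.data$session_id) %>%
    dplyr::summarise(
      n_unclassified = sum(.data$portal_function == "Unclassified"),
      .groups = "drop")

  out <- session_info %>%
    dplyr::left_join(counts, by = "session_id") %>%
    dplyr::left_join(uncl, by = "session_id") %>%
    dplyr::mutate(dplyr::across(dplyr::all_of(c(fns, "n_unclassified")),
                                ~ tidyr::replace_na(.x, 0L)))
  cnt <- as.matrix(out[, fns])
  out$comprehensiveness <- as.integer(rowSums(cnt > 0))
  out$is_valid <- out$duration_seconds > 0
  out[, c("session_id", "patient_id", "start_time", "device",
          "duration_seconds", fns, "n_unclassified", "comprehensiveness",
          "is_valid")]
}

#' Per-patient usage metrics
#'
#' Aggregates session metrics to the patient level. Function counts sum
#' over *valid* sessions only (sessions with nonzero duration), matching
#' the convention that descriptive statistics use valid sessions;
#' comprehensiveness is recomputed from the patient's pooled counts. A
#' patient is active iff they have at least two valid sessions. Set
#' `valid_only = FALSE` for the unfiltered variant.
#'
#' @param sm Session metrics from [session_metrics()].
#' @param valid_only Aggregate over valid sessions only (default TRUE).
#' @return Tibble with one row per patient appearing in `sm`:
#'   `patient_id`, `n_sessions_total`, `n_sessions_valid`, per-function
#'   counts, `comprehensiveness`, `is_active`.
#' @export
patient_metrics <- function(sm, valid_only = TRUE) {
  fns <- portal_functions()
  use <- if (valid_only) sm[sm$is_valid, , drop = FALSE] else sm
  totals <- sm %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::summarise(n_sessions_total = dplyr::n(),
                     n_sessions_valid = sum(.data$is_valid),
                     .groups = "drop")
  sums <- use %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(fns), sum), .groups = "drop")
  out <- totals %>%
    dplyr::left_join(sums, by = "patient_id") %>%
    dplyr::mutate(dplyr::across(dplyr::all_of(fns), ~ tidyr::replace_na(.x, 0L)))
  cnt <- as.matrix(out[, fns])
  out$comprehensiveness <- as.integer(rowSums(cnt > 0))
  out$is_active <- out$n_sessions_valid >= 2L
  out
}

#' Cohort-level summary of portal use
#'
#' Headline descriptive statistics over valid sessions and active patients:
#' session and patient totals, per-patient valid-session count
#' median/IQR/max, comprehensiveness histograms at both levels, and the
#' fraction of valid sessions touching more than one portal function.
#'
#' @param patients Patient metrics from [patient_metrics()].
#' @param sessions Session metrics from [session_metrics()].
#' @return List with `totals` (one-row tibble), `session_comprehensiveness`
#'   and `patient_comprehensiveness` histograms (count 0-8, n, percent).
#' @export
cohort_summary <- function(patients, sessions) {
  valid <- sessions[sessions$is_valid, , drop = FALSE]
  active <- patients[patients$is_active, , drop = FALSE]
  per_patient <- patients$n_sessions_valid[patients$is_active]

  hist_of <- function(x, n_total) {
    tibble::tibble(n_functions = 0:8) %>%
      dplyr::mutate(n = vapply(.data$n_functions,
                               function(k) sum(x == k), integer(1)),
                    percent = if (n_total > 0) 100 * .data$n / n_total else 0)
  }
  totals <- tibble::tibble(
    n_sessions_total = nrow(sessions),
    n_sessions_valid = nrow(valid),
    n_patients_total = nrow(patients),
    n_patients_active = nrow(active),
    sessions_per_patient_median = if (length(per_patient))
      stats::median(per_patient) else NA_real_,
    sessions_per_patient_iqr = if (length(per_patient))
      stats::IQR(per_patient, type = 7) else NA_real_,
    sessions_per_patient_max = if (length(per_patient))
      max(per_patient) else NA_integer_,
    frac_sessions_multi_function = if (nrow(valid))
      mean(valid$comprehensiveness > 1) else NA_real_
  )
  list(
    totals = totals,
    session_comprehensiveness = hist_of(valid$comprehensiveness, nrow(valid)),
    patient_comprehensiveness = hist_of(active$comprehensiveness, nrow(active))
  )
}
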