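#' Configuration for the synthetic-cohort generator
#'
#' Builds the parameter set for [simulate_cohort()]. Defaults emulate the
#' statistical structure reported for outpatient-portal audit data:
#' right-skewed session counts per patient, an approximately log-normal
#' body of inter-action gaps, predominantly single-function sessions, a
#' ~6% share of abandoned log-ins (zero-duration sessions), and the two
#' artifact classes — server keep-alive log-outs stamped ~21 minutes after
#' the last action of idle desktop sessions, and mobile duplicate bursts at
#' 2-second spacing.
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed; fully determines the output.
#' @param start_date Start of the observation window.
#' @param window_days Length of the window over which first sessions are
#'   spread (days).
#' @param sessions_per_patient Negative-binomial parameters
#'   (`size`, `mu`); each patient gets `1 + rnbinom(...)` sessions.
#' @param n_actions Negative-binomial (`size`, `mu`) for real (non-
#'   auxiliary) actions per engaged session; each gets `1 + rnbinom(...)`.
#' @param p_abandoned Probability a session is a bare log-in with no
#'   actions (invalid, zero duration).
#' @param within_gap Log-normal (`meanlog`, `sdlog`) for within-session
#'   gaps, seconds; draws are rounded to whole seconds, floored at 1 and
#'   capped at `threshold_seconds`.
#' @param between_gap Log-normal (`meanlog`, `sdlog`) for gaps between a
#'   patient's sessions; draws are floored at
#'   `threshold_seconds + between_gap_margin` so true boundaries always
#'   exceed the threshold.
#' @param between_gap_margin Seconds added to the floor (default 60).
#' @param threshold_seconds Inactivity threshold the generator respects.
#' @param function_mixture Named probability vector over the eight portal
#'   functions: each session draws its goal function from it. `Resources`
#'   defaults to 0 — those interactions are not captured in audit logs.
#' @param p_second_function Probability a session touches a second
#'   function.
#' @param p_mobile Probability a session is mobile.
#' @param p_agent_missing Probability a log-in carries no user agent
#'   (device then unknowable).
#' @param p_manual_logout Probability an engaged session ends with a
#'   patient-issued log-out.
#' @param keepalive_logout Inject the keep-alive artifact: idle-terminated
#'   desktop sessions get a server log-out `keepalive_delay` seconds
#'   (uniform range) after their last activity.
#' @param keepalive_delay Two-vector delay range, seconds.
#' @param mobile_duplicates Inject duplicate bursts in mobile sessions.
#' @param p_burst Probability a mobile action triggers a burst.
#' @param burst_extra Negative-binomial (`size`, `mu`) for the number of
#'   extra copies per burst (`1 +` draw), at `burst_spacing`-second
#'   intervals.
#' @param burst_spacing Seconds between burst copies (default 2).
#' @param missing_session_num_before Timestamp (or `NULL`): server session
#'   numbers are blanked for records before it, emulating untracked early
#'   logs.
#' @param multiday_session_num Fraction of patients whose server session
#'   number erroneously spans all their sessions.
#' @param status_mixture Named probabilities over account-status
#'   categories.
#' @param p_deceased Probability an inactivated account's closing comment
#'   reads "patient deceased".
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 50,
                       seed = 1,
                       start_date = "2015-07-01",
                       window_days = 1280,
                       sessions_per_patient = list(size = 1.2, mu = 12),
                       n_actions = list(size = 2, mu = 4),
                       p_abandoned = 0.06,
                       within_gap = list(meanlog = 3.2, sdlog = 1.1),
                       between_gap = list(meanlog = log(86400), sdlog = 1.3),
                       between_gap_margin = 60,
                       threshold_seconds = default_threshold_seconds(),
                       function_mixture = c(
                         "Messaging" = 0.32, "Visits" = 0.22,
                         "My record" = 0.30, "Medical tools" = 0.01,
                         "Billing" = 0.09, "Resources" = 0,
                         "Proxy" = 0.02, "Preferences" = 0.04),
                       p_second_function = 0.17,
                       p_mobile = 0.4,
                       p_agent_missing = 0.05,
                       p_manual_logout = 0.6,
                       keepalive_logout = TRUE,
                       keepalive_delay = c(1200, 1320),
                       mobile_duplicates = TRUE,
                       p_burst = 0.3,
                       burst_extra = list(size = 1, mu = 2),
                       burst_spacing = 2,
                       missing_session_num_before = "2016-05-15",
                       multiday_session_num = 0.1,
                       status_mixture = c(
                         "Activated" = 0.9399, "Inactivated" = 0.0534,
                         "Patient declined" = 0.0016,
                         "Pending activation" = 0.0052),
                       p_deceased = 125 / 134) {
  cfg <- as.list(environment())
  probs <- c(function_mixture, status_mixture, p_abandoned, p_second_function,
             p_mobile, p_agent_missing, p_manual_logout, p_burst, p_deceased)
  if (any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  # printed percentage tables can carry rounding residue; renormalize
  if (abs(sum(function_mixture) - 1) > 1e-3) {
    stop("function_mixture must sum to 1", call. = FALSE)
  }
  if (abs(sum(status_mixture) - 1) > 1e-3) {
    stop("status_mixture must sum to 1", call. = FALSE)
  }
  cfg$function_mixture <- function_mixture / sum(function_mixture)
  cfg$status_mixture <- status_mixture / sum(status_mixture)
  if (!all(names(function_mixture) %in% portal_functions())) {
    stop("function_mixture has unknown function names", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Per-function action-label vocabulary drawn from the shipped taxonomy:
# labels whose display string is itself the raw pattern.
taxonomy_label_pool <- function(taxonomy) {
  e <- taxonomy$entries
  bare <- e[is.na(e$extended) & !e$substring & e$fun != "Miscellaneous", ]
  bare <- bare[tolower(trimws(bare$label)) == bare$action, ]
  split(bare$label, bare$fun)
}

#' Simulate a synthetic portal cohort with ground truth
#'
#' Generates an audit log and an account-status history in the Clarity
#' export schema, together with the ground truth needed to score every
#' pipeline stage: true session boundaries, per-session pre-artifact
#' function counts, true device, and true account status. Output is fully
#' determined by `config$seed`; emitted files parse through
#' [read_audit_log()] with zero rejects.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory: writes `audit.tsv` and `status.tsv`
#'   there.
#' @return List with `audit` (an `audit_log`, already in canonical order),
#'   `status` (status-event tibble), `truth` (list: `sessions` tibble,
#'   `record_session` integer vector aligned with audit rows, `status`
#'   tibble), and `paths` (if `dir` given).
#' @export
simulate_cohort <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  taxonomy <- load_taxonomy()
  pool <- taxonomy_label_pool(taxonomy)
  fns <- portal_functions()
  mix <- config$function_mixture[fns[fns %in% names(config$function_mixture)]]
  mix <- mix[mix > 0]
  ext_vocab <- c("view", "list", "detail", "submit")
  t0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")

  audit_rows <- list()
  truth_rows <- list()
  rec_session <- list()
  status_rows <- list()
  sess_uid <- 0L

  n <- config$n_patients
  pids <- if (n > 0) sprintf("P%05d", seq_len(n)) else character()

  for (p in seq_len(n)) {
    pid <- pids[p]
    n_sess <- 1L + stats::rnbinom(1, size = config$sessions_per_patient$size,
                                  mu = config$sessions_per_patient$mu)
    multiday <- stats::runif(1) < config$multiday_session_num
    shared_num <- sprintf("%s-SRV0", pid)
    cursor <- t0 + round(stats::runif(1, 0, config$window_days * 86400))

    first_session_start <- cursor
    for (s in seq_len(n_sess)) {
      sess_uid <- sess_uid + 1L
      mobile <- stats::runif(1) < config$p_mobile
      agent <- if (stats::runif(1) < config$p_agent_missing) NA_character_
        else if (mobile) sample(c("EpicMyChart-iPhone", "EpicMyChart-Android"), 1)
        else "Mozilla/5.0 (Windows NT 10.0; Win64; x64) AppleWebKit/537.36"
      srv <- if (multiday) shared_num else sprintf("%s-SRV%d", pid, s)
      abandoned <- stats::runif(1) < config$p_abandoned

      goal <- sample(names(mix), 1, prob = mix)
      funs_used <- goal
      if (stats::runif(1) < config$p_second_function && length(mix) > 1) {
        rest <- mix[names(mix) != goal]
        funs_used <- c(goal, sample(names(rest), 1, prob = rest))
      }

      draw_gap <- function() {
        min(config$threshold_seconds,
            max(1, round(stats::rlnorm(1, config$within_gap$meanlog,
                                       config$within_gap$sdlog))))
      }

      ts <- cursor
      rows <- list(list(ts = ts, action = "Login", ext = NA_character_,
                        agent = agent, real = FALSE))
      counts <- stats::setNames(integer(length(fns)), fns)
      prev_pair <- c("Login", NA)

      if (!abandoned) {
        n_act <- 1L + stats::rnbinom(1, size = config$n_actions$size,
                                     mu = config$n_actions$mu)
        for (k in seq_len(n_act)) {
          ts <- ts + draw_gap()
          fn <- if (length(funs_used) > 1 && stats::runif(1) < 0.35)
            funs_used[2] else funs_used[1]
          lab <- sample(pool[[fn]], 1)
          ext <- sample(ext_vocab, 1)
          if (identical(lab, prev_pair[1]) && identical(ext, prev_pair[2])) {
            ext <- ext_vocab[(match(ext, ext_vocab) %% length(ext_vocab)) + 1L]
          }
          prev_pair <- c(lab, ext)
          counts[fn] <- counts[fn] + 1L
          rows[[length(rows) + 1L]] <-
            list(ts = ts, action = lab, ext = ext, agent = NA_character_,
                 real = TRUE)
          if (mobile && config$mobile_duplicates &&
              stats::runif(1) < config$p_burst) {
            n_extra <- 1L + stats::rnbinom(1, size = config$burst_extra$size,
                                           mu = config$burst_extra$mu)
            for (d in seq_len(n_extra)) {
              ts <- ts + config$burst_spacing
              rows[[length(rows) + 1L]] <-
                list(ts = ts, action = lab, ext = ext, agent = NA_character_,
                     real = FALSE)
            }
          }
        }
      }

      manual_logout <- !abandoned && stats::runif(1) < config$p_manual_logout
      if (manual_logout) {
        ts <- ts + draw_gap()
        rows[[length(rows) + 1L]] <-
          list(ts = ts, action = "Logout", ext = "Logout",
               agent = NA_character_, real = FALSE)
      } else if (!mobile && config$keepalive_logout) {
        ts <- ts + round(stats::runif(1, config$keepalive_delay[1],
                                      config$keepalive_delay[2]))
        rows[[length(rows) + 1L]] <-
          list(ts = ts, action = "Logout", ext = "Logout",
               agent = NA_character_, real = FALSE)
      }

      sess_tbl <- tibble::tibble(
        patient_id = pid,
        timestamp = as.POSIXct(vapply(rows, function(r) as.numeric(r$ts),
                                      numeric(1)),
                               origin = "1970-01-01", tz = "UTC"),
        action_type = vapply(rows, function(r) r$action, character(1)),
        extended_info = vapply(rows, function(r) r$ext, character(1)),
        server_session = srv,
        user_agent = vapply(rows, function(r) r$agent, character(1))
      )
      audit_rows[[sess_uid]] <- sess_tbl
      rec_session[[sess_uid]] <- rep(sess_uid, nrow(sess_tbl))

      nonlogout <- sess_tbl$timestamp[sess_tbl$action_type != "Logout"]
      truth_rows[[sess_uid]] <- tibble::tibble(
        patient_id = pid, true_session = sess_uid,
        start_time = sess_tbl$timestamp[1],
        device = if (mobile) "mobile" else "desktop",
        login_has_agent = !is.na(agent),
        n_records = nrow(sess_tbl),
        duration_seconds = if (length(nonlogout) >= 2)
          as.integer(max(as.numeric(nonlogout)) - min(as.numeric(nonlogout)))
          else 0L,
        !!!as.list(counts)
      )

      between <- max(config$threshold_seconds + config$between_gap_margin,
                     round(stats::rlnorm(1, config$between_gap$meanlog,
                                         config$between_gap$sdlog)))
      cursor <- ts + between
    }

    status <- sample(names(config$status_mixture), 1,
                     prob = config$status_mixture)
    reg <- first_session_start - round(stats::runif(1, 7, 90)) * 86400
    ev <- switch(status,
      "Activated" = tibble::tibble(
        patient_id = pid,
        status = c("Pending activation", "Activated"),
        timestamp = c(reg, reg + 3600),
        method = "WEB", comment = NA_character_),
      "Inactivated" = {
        deceased <- stats::runif(1) < config$p_deceased
        tibble::tibble(
          patient_id = pid,
          status = c("Pending activation", "Activated", "Inactivated"),
          timestamp = c(reg, reg + 3600,
                        first_session_start + 400 * 86400),
          method = "WEB",
          comment = c(NA, NA,
                      if (deceased) "patient deceased" else "user request"))
      },
      "Patient declined" = tibble::tibble(
        patient_id = pid, status = "Patient declined", timestamp = reg,
        method = "WEB", comment = NA_character_),
      "Pending activation" = tibble::tibble(
        patient_id = pid, status = "Pending activation", timestamp = reg,
        method = "WEB", comment = NA_character_)
    )
    status_rows[[p]] <- ev
  }

  audit <- dplyr::bind_rows(audit_rows)
  record_session <- unlist(rec_session) %||% integer()
  truth_sessions <- dplyr::bind_rows(truth_rows)
  status <- dplyr::bind_rows(status_rows)
  if (nrow(status) == 0L) {
    status <- tibble::tibble(patient_id = character(), status = character(),
                             timestamp = as.POSIXct(character(), tz = "UTC"),
                             method = character(), comment = character())
  }
  if (nrow(audit) == 0L) {
    audit <- tibble::tibble(patient_id = character(),
                            timestamp = as.POSIXct(character(), tz = "UTC"),
                            action_type = character(),
                            extended_info = character(),
                            server_session = character(),
                            user_agent = character())
    record_session <- integer()
  }
  if (!is.null(config$missing_session_num_before) && nrow(audit)) {
    cutoff <- as.POSIXct(paste(config$missing_session_num_before, "00:00:00"),
                         tz = "UTC")
    audit$server_session[audit$timestamp < cutoff] <- NA_character_
  }

  alog <- as_audit_log(audit)
  attr(alog, "sorted") <- TRUE  # emitted per patient in time order, no ties

  truth <- list(sessions = truth_sessions, record_session = record_session,
                status = tibble::tibble(
                  patient_id = pids,
                  status = if (n > 0) vapply(status_rows, function(e)
                    e$status[nrow(e)], character(1)) else character()))
  out <- list(audit = alog, status = status, truth = truth)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    audit_path <- file.path(dir, "audit.tsv")
    status_path <- file.path(dir, "status.tsv")
    write_audit_log(alog, audit_path)
    st <- tibble::tibble(
      PAT_MRN_ID = status$patient_id,
      MYC_STATUS_HX = status$status,
      MYC_STATUS_TMSTP = format(status$timestamp, "%Y-%m-%d %H:%M:%S"),
      MYC_STATUS_MTHD = ifelse(is.na(status$method), "Null", status$method),
      MYC_STATUS_CMT = ifelse(is.na(status$comment), "Null", status$comment))
    readr::write_delim(st, status_path, delim = "\t", na = "Null",
                       progress = FALSE)
    out$paths <- list(audit = audit_path, status = status_path)
  }
  out
}

#' Score pipeline recovery against generator ground truth
#'
#' Compares the recovered sessionization and metrics with the known truth
#' of a simulated cohort. Boundary precision and recall are computed on
#' non-log-out records: a server keep-alive log-out stamped beyond the
#' threshold correctly splits into a log-out-only session (that split *is*
#' the artifact correction), so engagement boundaries are defined on real
#' actions. Device accuracy is scored on sessions whose log-in carried a
#' user agent. Count error compares patient-level per-function counts
#' (over valid sessions) with pre-artifact truth.
#'
#' @param truth `truth` component of [simulate_cohort()] output.
#' @param slog The `session_log` obtained by running [assign_sessions()] on
#'   the emitted audit log (row-aligned with it).
#' @param session_info Session attributes from [session_table()].
#' @param patients Patient metrics from [patient_metrics()].
#' @param logout_labels Log-out action types.
#' @return List: `boundary_precision`, `boundary_recall`,
#'   `device_accuracy`, `n_device_scored`, `count_abs_error`,
#'   `count_error_rate` (absolute error over total true count).
#' @export
score_recovery <- function(truth, slog, session_info, patients,
                           logout_labels = "Logout") {
  stopifnot(inherits(slog, "session_log"))
  if (nrow(slog) != length(truth$record_session)) {
    stop("session log is not row-aligned with the ground truth", call. = FALSE)
  }
  mask <- !(tolower(slog$action_type) %in% tolower(logout_labels))
  true_id <- truth$record_session[mask]
  pred_id <- slog$session_id[mask]
  m <- length(true_id)
  true_start <- if (m) c(TRUE, true_id[-1L] != true_id[-m]) else logical()
  pred_start <- if (m) c(TRUE, pred_id[-1L] != pred_id[-m]) else logical()
  tp <- sum(true_start & pred_start)
  precision <- if (sum(pred_start)) tp / sum(pred_start) else NA_real_
  recall <- if (sum(true_start)) tp / sum(true_start) else NA_real_

  # device: predicted session containing each true session's first record
  first_idx <- which(mask)[which(true_start)]
  dev_tbl <- tibble::tibble(
    true_session = true_id[true_start],
    session_id = slog$session_id[first_idx]) %>%
    dplyr::left_join(truth$sessions[, c("true_session", "device",
                                        "login_has_agent")],
                     by = "true_session") %>%
    dplyr::left_join(session_info[, c("session_id", "device")],
                     by = "session_id", suffix = c("_true", "_pred")) %>%
    dplyr::filter(.data$login_has_agent)
  device_accuracy <- if (nrow(dev_tbl))
    mean(dev_tbl$device_pred == dev_tbl$device_true) else NA_real_

  fns <- portal_functions()
  true_counts <- truth$sessions %>%
    dplyr::filter(.data$duration_seconds > 0) %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(fns), sum), .groups = "drop")
  cmp <- dplyr::full_join(true_counts, patients[, c("patient_id", fns)],
                          by = "patient_id", suffix = c("_true", "_pred"))
  tm <- as.matrix(cmp[, paste0(fns, "_true")])
  pm <- as.matrix(cmp[, paste0(fns, "_pred")])
  tm[is.na(tm)] <- 0; pm[is.na(pm)] <- 0
  abs_err <- sum(abs(tm - pm))

  list(boundary_precision = precision,
       boundary_recall = recall,
       device_accuracy = device_accuracy,
       n_device_scored = nrow(dev_tbl),
       count_abs_error = abs_err,
       count_error_rate = abs_err / max(1, sum(tm)))
}
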