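# Shared fixtures and independent oracles.

`%||%` <- function(a, b) if (is.null(a)) b else a

example_log_path <- function() {
  system.file("extdata", "example_access_log.tsv", package = "portalog",
              mustWork = TRUE)
}

# Build an audit_log from compact arguments (timestamps as offsets in
# seconds from a fixed origin).
mk_log <- function(patient, offset, action, extended = NA, agent = NA,
                   sorted = TRUE) {
  origin <- as.POSIXct("2018-01-01 00:00:00", tz = "UTC")
  log <- as_audit_log(data.frame(
    patient_id = patient,
    timestamp = origin + offset,
    action_type = action,
    extended_info = extended,
    user_agent = agent
  ))
  if (sorted) canonical_sort(log) else log
}

# Independent single-pass reference sessionizer, written against the
# boundary rules directly: new session at first record of a patient, at
# any log-in, after a gap strictly greater than the threshold, and after
# a log-out. Deliberately naive (row loop, no vectorization).
ref_sessionize <- function(log, threshold) {
  n <- nrow(log)
  sid <- integer(n)
  cur <- 0L
  prev_pat <- ""
  prev_ts <- NA_real_
  prev_logout <- FALSE
  for (i in seq_len(n)) {
    a <- tolower(log$action_type[i])
    ts <- as.numeric(log$timestamp[i])
    new <- log$patient_id[i] != prev_pat || a == "login" ||
      (ts - prev_ts) > threshold || prev_logout
    if (new) cur <- cur + 1L
    sid[i] <- cur
    prev_pat <- log$patient_id[i]
    prev_ts <- ts
    prev_logout <- a == "logout"
  }
  sid
}

# Canonical form of a partition label vector, for comparing partitions
# regardless of how the labels are spelled.
partition_of <- function(labels) match(labels, unique(labels))

# Random fuzzed log: a few patients, gaps straddling the threshold,
# actions mixing log-ins/log-outs with taxonomy and unknown labels.
rand_log <- function(n_records, threshold, n_patients = 3) {
  actions <- c("Login", "Logout", "Message center", "Test results",
               "Schedule an appointment", "Bill payment", "Allergies",
               "UnknownWidget")
  pats <- sprintf("Z%02d", sample.int(n_patients, n_records, replace = TRUE))
  offs <- unlist(lapply(split(seq_len(n_records), pats), function(idx) {
    cumsum(sample(c(1:60, threshold - 1, threshold, threshold + 1,
                    threshold * 2), length(idx), replace = TRUE))
  }))
  # reassemble in patient blocks so offsets are per patient
  ord <- order(pats)
  mk_log(patient = pats[ord],
         offset = offs,
         action = sample(actions, n_records, replace = TRUE,
                         prob = c(.15, .1, .2, .2, .15, .1, .05, .05)),
         extended = sample(c(NA, "view", "list"), n_records, replace = TRUE))
}

# Full metrics path on an audit_log, used by property tests.
run_metrics_path <- function(log, threshold = 1256,
                             taxonomy = load_taxonomy(), dedup = TRUE) {
  slog <- assign_sessions(log, threshold)
  info <- session_table(slog)
  slog <- categorize(slog, taxonomy)
  dd <- if (dedup) dedup_actions(slog) else slog
  sm <- session_metrics(dd, info)
  list(slog = slog, dedup = dd, info = info, sessions = sm,
       patients = patient_metrics(sm))
}
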