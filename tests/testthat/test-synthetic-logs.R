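test_that("simulation is deterministic under seed and parses with zero rejects", {
  cfg <- sim_config(n_patients = 20, seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_cohort(cfg, dir = d1)
  s2 <- simulate_cohort(cfg, dir = d2)
  expect_identical(readLines(s1$paths$audit), readLines(s2$paths$audit))
  expect_identical(readLines(s1$paths$status), readLines(s2$paths$status))

  log <- read_audit_log(s1$paths$audit)
  expect_equal(ingest_report(log)$n_rejected, 0L)
  expect_equal(nrow(log), nrow(s1$audit))
  # emitted order is already canonical
  resorted <- canonical_sort(log)
  expect_equal(resorted$timestamp, s1$audit$timestamp)
  expect_equal(resorted$action_type, s1$audit$action_type)
})

test_that("an empty cohort yields empty files and truth", {
  d <- withr::local_tempdir()
  s <- simulate_cohort(sim_config(n_patients = 0, seed = 1), dir = d)
  expect_equal(nrow(s$audit), 0L)
  expect_equal(nrow(s$status), 0L)
  expect_length(s$truth$record_session, 0L)
  expect_equal(nrow(read_audit_log(s$paths$audit)), 0L)
})

test_that("invalid generator configurations are rejected", {
  expect_error(sim_config(p_mobile = 1.5), "probabilities")
  expect_error(sim_config(function_mixture = c(Messaging = 0.5, Visits = 0.2)),
               "sum to 1")
})

test_that("keep-alive log-outs land 1200-1320 s after last activity on idle desktop sessions", {
  # tight within-session gaps so patient-issued log-outs stay well below
  # the keep-alive band and the two are separable in the check
  sim <- simulate_cohort(sim_config(n_patients = 50, seed = 5, p_mobile = 0,
                                    keepalive_logout = TRUE,
                                    within_gap = list(meanlog = 3.2,
                                                      sdlog = 0.8)))
  log <- sim$audit
  delays <- c()
  for (sid in unique(sim$truth$record_session)) {
    rows <- which(sim$truth$record_session == sid)
    acts <- log$action_type[rows]
    if (acts[length(acts)] != "Logout") next
    nonlogout <- rows[acts != "Logout"]
    delay <- as.numeric(log$timestamp[rows[length(rows)]]) -
      as.numeric(log$timestamp[max(nonlogout)])
    delays <- c(delays, delay)
  }
  # manual log-outs sit within a short gap; keep-alive ones in the band
  keepalive <- delays[delays > 1000]
  expect_gt(length(keepalive), 10)
  expect_true(all(keepalive >= 1200 & keepalive <= 1320))
})

test_that("recovery is perfect with artifacts off and boundaries above threshold", {
  sim <- simulate_cohort(sim_config(n_patients = 30, seed = 13,
                                    keepalive_logout = FALSE,
                                    mobile_duplicates = FALSE))
  res <- run_metrics_path(sim$audit)
  rec <- score_recovery(sim$truth, res$slog, res$info, res$patients)
  expect_equal(rec$boundary_precision, 1)
  expect_equal(rec$boundary_recall, 1)
  expect_equal(rec$count_abs_error, 0)
  expect_equal(rec$device_accuracy, 1)
})

test_that("pipeline recovery ignores unreliable server session numbers", {
  base <- sim_config(n_patients = 25, seed = 17, multiday_session_num = 0)
  warped <- sim_config(n_patients = 25, seed = 17, multiday_session_num = 0.6)
  for (cfg in list(base, warped)) {
    sim <- simulate_cohort(cfg)
    res <- run_metrics_path(sim$audit)
    rec <- score_recovery(sim$truth, res$slog, res$info, res$patients)
    expect_equal(rec$boundary_recall, 1)
    expect_equal(rec$count_abs_error, 0)
  }
})

test_that("emitted within-session gaps follow the configured log-normal", {
  cfg <- sim_config(n_patients = 170, seed = 23,
                    keepalive_logout = FALSE, mobile_duplicates = FALSE)
  sim <- simulate_cohort(cfg)
  log <- sim$audit
  same <- c(FALSE, diff(sim$truth$record_session) == 0)
  gaps <- as.numeric(log$timestamp[same]) -
    as.numeric(log$timestamp[which(same) - 1L])
  expect_gte(length(gaps), 10000)
  gaps <- gaps[seq_len(10000)]
  # de-discretize the whole-second quantization before the KS check
  set.seed(1)
  jittered <- gaps + stats::runif(length(gaps), -0.5, 0.5)
  ks <- stats::ks.test(jittered, stats::plnorm,
                       meanlog = cfg$within_gap$meanlog,
                       sdlog = cfg$within_gap$sdlog)
  expect_gt(ks$p.value, 0.01)
})
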