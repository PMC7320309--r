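test_that("dedup collapses consecutive identical runs only", {
  # mobile burst: five identical records 2 s apart collapse to one
  burst <- assign_sessions(
    mk_log("p", c(0, 2, 4, 6, 8), "Visits", extended = "Get future appt list"),
    1256)
  expect_equal(nrow(dedup_actions(burst)), 1L)
  # alternating values never collapse (no consecutive identical pair)
  alt <- assign_sessions(
    mk_log("p", c(0, 3, 6), "Messaging",
           extended = c("Inbox message list", "Message read",
                        "Inbox message list")), 1256)
  expect_equal(nrow(dedup_actions(alt)), 3L)
  single <- assign_sessions(mk_log("p", 0, "Visits"), 1256)
  expect_equal(nrow(dedup_actions(single)), 1L)
  # identical values across a session boundary are not a duplicate run
  crossing <- assign_sessions(
    mk_log("p", c(0, 2000), "Visits", extended = "x"), 1256)
  expect_equal(nrow(dedup_actions(crossing)), 2L)
  # optional interval cap keeps slow legitimate repeats
  slow <- assign_sessions(
    mk_log("p", c(0, 600), "Visits", extended = "x"), 1256)
  expect_equal(nrow(dedup_actions(slow, max_interval = 60)), 2L)
  expect_equal(nrow(dedup_actions(slow)), 1L)
})

test_that("dedup is idempotent and never increases counts", {
  set.seed(51)
  tax <- load_taxonomy()
  for (i in 1:30) {
    slog <- categorize(assign_sessions(rand_log(sample(5:80, 1), 300), 300),
                       tax)
    once <- dedup_actions(slog)
    twice <- dedup_actions(once)
    expect_identical(tibble::as_tibble(once), tibble::as_tibble(twice))
    expect_lte(nrow(once), nrow(slog))
  }
})

test_that("session metrics implement the frequency and comprehensiveness definitions", {
  log <- canonical_sort(read_audit_log(example_log_path()))
  res <- run_metrics_path(log)
  sm <- res$sessions
  # second session: the identical pair collapses to one Messaging action
  expect_equal(sm$Messaging[2], 1L)
  expect_equal(sm$comprehensiveness[2], 1L)
  expect_true(sm$is_valid[2])
  # a session of auxiliary actions only carries zero counts
  aux <- run_metrics_path(mk_log("p", c(0, 5), c("Login", "Logout")))
  expect_equal(aux$sessions$comprehensiveness, 0L)
  expect_false(aux$sessions$is_valid)
  # two functions in one session
  duo <- run_metrics_path(
    mk_log("p", c(0, 10), c("Message center", "Bill payment")))
  expect_equal(duo$sessions$comprehensiveness, 2L)
  # comprehensiveness equals the count of nonzero functions exactly
  fns <- portal_functions()
  expect_equal(sm$comprehensiveness,
               as.integer(rowSums(as.matrix(sm[, fns]) > 0)))
})

test_that("patient metrics aggregate valid sessions and flag activity", {
  two <- run_metrics_path(mk_log(
    "p", c(0, 10, 5000, 5010),
    c("Message center", "Message center", "Appointment details",
      "Appointment details"),
    extended = c("a", "b", "a", "b")))
  pm <- two$patients
  expect_equal(pm$comprehensiveness, 2L)
  expect_true(pm$is_active)
  expect_equal(pm$n_sessions_valid, 2L)

  one <- run_metrics_path(mk_log("p", c(0, 10), "Message center",
                                 extended = c("a", "b")))
  expect_false(one$patients$is_active)

  # unfiltered variant counts invalid sessions too
  mixed <- run_metrics_path(mk_log(
    "p", c(0, 10, 5000), c("Message center", "Message center", "Bill payment"),
    extended = c("a", "b", "a")))
  expect_equal(patient_metrics(mixed$sessions, valid_only = TRUE)$Billing, 0L)
  expect_equal(patient_metrics(mixed$sessions, valid_only = FALSE)$Billing, 1L)
})

test_that("unclassified records are reported but never counted", {
  res <- run_metrics_path(mk_log(
    "p", c(0, 5), c("Message center", "MysteryAction")))
  expect_equal(res$sessions$n_unclassified, 1L)
  expect_equal(res$sessions$comprehensiveness, 1L)
  expect_equal(sum(as.matrix(res$sessions[, portal_functions()])), 1)
})

test_that("cohort summary histograms and fractions partition the totals", {
  res <- run_metrics_path(mk_log(
    rep(c("a", "b", "c"), each = 2),
    rep(c(0, 10), 3),
    c("Message center", "Message center",
      "Message center", "Bill payment",
      "Test results", "Test results"),
    extended = rep(c("x", "y"), 3)))
  cs <- cohort_summary(res$patients, res$sessions)
  # three valid sessions with comprehensiveness {1, 2, 1}
  expect_equal(cs$totals$n_sessions_valid, 3L)
  expect_equal(cs$totals$frac_sessions_multi_function, 1 / 3)
  expect_equal(sum(cs$session_comprehensiveness$n),
               cs$totals$n_sessions_valid)
  expect_equal(sum(cs$patient_comprehensiveness$n),
               cs$totals$n_patients_active)
})
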