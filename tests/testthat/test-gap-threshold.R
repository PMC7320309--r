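mk_gaps <- function(g, logout = FALSE) {
  tibble::tibble(
    patient_id = "p1", gap_seconds = as.integer(g),
    current_action_is_logout = rep_len(logout, length(g)),
    timestamp = as.POSIXct("2018-01-01", tz = "UTC") + cumsum(g))
}

test_that("gaps reproduce the printed excerpt's hand-computed values", {
  log <- canonical_sort(read_audit_log(example_log_path()))
  gaps <- compute_gaps(log)
  expect_equal(nrow(gaps), 13L)      # first record has no predecessor
  expect_equal(gaps$gap_seconds[2], 754L)   # 12:40:38 -> 12:53:12
  expect_equal(gaps$gap_seconds[3], 3232L)  # 12:53:12 -> 13:47:04
  expect_true(gaps$current_action_is_logout[13])
  expect_false(any(gaps$current_action_is_logout[-13]))
  expect_true(all(gaps$gap_seconds >= 0))
})

test_that("single-record patients yield no observations and unsorted input errors", {
  log <- mk_log(c("a", "b"), c(0, 100), c("Login", "Login"))
  gaps <- compute_gaps(log)
  expect_equal(nrow(gaps), 0L)
  unsorted <- as_audit_log(data.frame(
    patient_id = "a", timestamp = as.POSIXct("2018-01-01", tz = "UTC"),
    action_type = "Login"))
  expect_error(compute_gaps(unsorted), "sorted")
})

test_that("threshold estimation matches the linear-interpolation quantile", {
  expect_equal(estimate_threshold(mk_gaps(c(10, 20, 30)),
                                  retention = 1)$threshold_seconds, 30)
  expect_equal(estimate_threshold(mk_gaps(0:100),
                                  retention = 0.5)$threshold_seconds, 50)
  # independent oracle: textbook interpolation between order statistics
  quantile_oracle <- function(x, p) {
    s <- sort(x)
    h <- (length(s) - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
  }
  set.seed(11)
  for (i in 1:500) {
    g <- sample.int(5000, sample.int(1000, 1), replace = TRUE)
    p <- stats::runif(1, 0.05, 1)
    expect_equal(estimate_threshold(mk_gaps(g), retention = p)$threshold_seconds,
                 quantile_oracle(g, p))
  }
})

test_that("threshold is non-decreasing in retention and excludes log-out gaps", {
  set.seed(3)
  g <- dplyr::bind_rows(mk_gaps(round(stats::rlnorm(2000, 3, 1))),
                        mk_gaps(rep(1260L, 300), logout = TRUE))
  rets <- c(0.5, 0.8, 0.95, 0.998, 1)
  th <- vapply(rets, function(p)
    estimate_threshold(g, retention = p)$threshold_seconds, numeric(1))
  expect_true(all(diff(th) >= 0))
  est <- estimate_threshold(g, retention = 0.998, exclude_logouts = TRUE)
  expect_equal(est$n_gaps_used, 2000L)
  expect_equal(est$n_gaps_excluded_logout, 300L)
  # the retention invariant: fraction of used gaps at or below the
  # threshold equals the retention within one quantile step
  frac <- mean(g$gap_seconds[!g$current_action_is_logout] <=
                 est$threshold_seconds)
  expect_lte(abs(frac - 0.998), 1 / 2000 + 1e-9)
})

test_that("estimation on an empty gap set instructs a fixed threshold", {
  g <- mk_gaps(rep(100L, 5), logout = TRUE)
  expect_error(estimate_threshold(g, exclude_logouts = TRUE), "fixed threshold")
  expect_error(estimate_threshold(mk_gaps(10), retention = 0), "retention")
})

test_that("the default fallback threshold is 1256 seconds", {
  expect_equal(default_threshold_seconds(), 1256)
})

test_that("gap density profile conserves mass and exposes the log-out spike", {
  prof <- gap_density_profile(mk_gaps(rep(60L, 100)), n_bins = 20)
  expect_equal(sum(prof$mass), 1, tolerance = 1e-9)
  expect_equal(max(prof$mass), 1)

  set.seed(5)
  body <- round(stats::rlnorm(5000, 3.2, 1.1))
  spike <- rep(1260L, 1000)
  g <- dplyr::bind_rows(mk_gaps(body), mk_gaps(spike, logout = TRUE))
  spike_mass <- function(prof) {
    sum(prof$mass[prof$bin_hi > 1200 & prof$bin_lo < 1320])
  }
  raw <- gap_density_profile(g, exclude_logouts = FALSE, n_bins = 60)
  cleaned <- gap_density_profile(g, exclude_logouts = TRUE, n_bins = 60)
  expect_equal(sum(raw$mass), 1, tolerance = 1e-9)
  expect_lt(spike_mass(cleaned), spike_mass(raw))
  # the excluded profile loses at least 90% of the injected spike mass
  injected <- 1000 / 6000
  expect_lt(spike_mass(raw) - spike_mass(cleaned) - injected, 0.1 * injected)
  expect_gt(spike_mass(raw) - spike_mass(cleaned), 0.9 * injected)
  expect_error(gap_density_profile(g, n_bins = 1), "n_bins")
})
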