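# portalog

Session-level usage metrics from outpatient-portal audit logs.

## What problem this solves

Electronic health record portals (e.g. Epic MyChart) log every patient
action server-side: a timestamped row with an action-type code
(`MYC_UA_TYPE_C`), free-text detail (`UA_EXTENDED_INFO`), a server session
number (`UA_SESSION_NUM`) and a client user agent (`UA_USER_AGENT`).
Researchers and quality-improvement teams want behavioral engagement
measures from these logs, but the raw data mislead in three specific ways:
the server session number is unreliable (untracked ranges, intermittent
assignment, multi-day "sessions"); idle desktop sessions end with a server
keep-alive log-out ~20 minutes after the last real action, inflating
durations into a spurious 20–22 minute mode; and the mobile client re-logs
the same action every ~2 seconds while a page stays open, inflating counts.

`portalog` re-derives sessions from timestamps and corrects both artifacts,
producing validated metrics at two levels of a four-level data model
(action → portal function → session → patient):

* **Frequency of use** — number of accesses to each portal function
  (Messaging, Visits, My record, Medical tools, Billing, Resources, Proxy,
  Preferences), per session and per patient;
* **Comprehensiveness of use** — number of distinct functions used
  (0–8), per session and per patient.

A **session** is a coherent, uninterrupted run of one patient's actions,
bounded by log-ins, log-outs, and inactivity greater than a threshold
**t**. The threshold is estimated from the data as the empirical
*p*-quantile (linear interpolation) of inter-action gaps after removing
log-out-attributed gaps:

    t = Q_p({ gap_i : later action of gap_i is not a log-out }),  p = 0.998

with 1256 s (~21 min) shipped as the fixed default. A session is **valid**
iff its effective duration — last minus first non-log-out timestamp — is
nonzero; a patient is **active** iff they have ≥ 2 valid sessions.

## Worked example

The package ships a 14-row audit-log excerpt (one patient, two days) as
`inst/extdata/example_access_log.tsv`:

```r
library(portalog)
path <- system.file("extdata", "example_access_log.tsv", package = "portalog")
res <- run_pipeline(pipeline_config(audit_path = path))
res$sessions[, c("session_id", "device", "duration_seconds",
                 "Messaging", "Visits", "comprehensiveness", "is_valid")]
#> # A tibble: 3 x 7
#>   session_id device  duration_seconds Messaging Visits comprehensiveness is_valid
#> 1 xxxxx-S1   unknown                0         1      0                 1 FALSE
#> 2 xxxxx-S2   unknown              754         1      0                 1 TRUE
#> 3 xxxxx-S3   mobile               195         4      4                 2 TRUE
```

Reading the output: the 14 records partition into three sessions — a lone
message-form action two days earlier (zero duration, hence invalid), a
two-action messaging session whose identical consecutive records
deduplicate to one Messaging access over 754 s, and an 11-record mobile
session (the log-in's `EpicMyChart-iPhone` agent) lasting 195 s — the
closing log-out 15 minutes later is excluded from the duration, and its
nine real actions deduplicate to 4 Messaging and 4 Visits accesses
(the auxiliary log-in/log-out are not counted; comprehensiveness 2).

```r
res$patients[, c("patient_id", "n_sessions_valid", "Messaging", "Visits",
                 "comprehensiveness", "is_active")]
#> # A tibble: 1 x 6
#>   patient_id n_sessions_valid Messaging Visits comprehensiveness is_active
#> 1 xxxxx                     2         5      4                 2 TRUE
```

Patient-level counts aggregate the two valid sessions (5 Messaging,
4 Visits accesses; 2 distinct functions; active).

A synthetic cohort with known ground truth, reproducing both artifact
classes, is available for end-to-end validation:

```r
sim <- simulate_cohort(sim_config(n_patients = 200, seed = 1))
slog <- assign_sessions(sim$audit, default_threshold_seconds())
info <- session_table(slog)
pm   <- patient_metrics(session_metrics(
          dedup_actions(categorize(slog, load_taxonomy())), info))
score_recovery(sim$truth, slog, info, pm)
```

A thin command-line driver wraps the same functions:

```sh
Rscript inst/cli/portal-sessions run --audit audit.tsv --status status.tsv --out out/
Rscript inst/cli/portal-sessions threshold --audit audit.tsv --retention 0.998
Rscript inst/cli/portal-sessions simulate --out sim/ --n-patients 50 --seed 1
```

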