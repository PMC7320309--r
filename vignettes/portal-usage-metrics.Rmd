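---
title: "From portal audit logs to usage metrics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From portal audit logs to usage metrics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(portalog)
```

## The problem

Outpatient portals (e.g. Epic MyChart) log every patient action server-side:
one timestamped row per action, with an action-type code, free-text detail,
a server-assigned session number, and the client user agent. Turning this
clickstream into defensible engagement metrics requires more than counting
rows. Three things get in the way:

1. **The server session number is unreliable.** It can be untracked for
   whole date ranges, assigned intermittently, or span several days of
   obviously separate visits. Sessionization must be re-derived from
   timestamps.
2. **Keep-alive log-outs.** When a desktop user walks away, the server
   eventually stamps a log-out roughly 20 minutes after the last real
   action. Raw "time in session" then shows a spurious second mode near
   20–22 minutes that measures the server timeout, not the patient.
3. **Mobile duplicate bursts.** The mobile client can re-log the same
   action every ~2 seconds while a page stays open, inflating frequency
   counts (but not durations).

`portalog` implements the full chain from raw delimited exports to
session-level and patient-level **frequency of use** (accesses per portal
function) and **comprehensiveness of use** (number of distinct functions
used), with both artifact classes corrected.

## The processing model

The pipeline runs eight ordered stages (`run_pipeline()` orchestrates them):

1. **Ingest** (`read_audit_log()`): parse the six Clarity-named columns,
   trim free text, map the literal `"Null"` and empty strings to `NA`, and
   reject — never silently drop — rows with unparseable timestamps.
2. **Canonical sort** (`canonical_sort()`): order by patient, then
   timestamp; within one second, log-ins first, log-outs last, remaining
   ties in stable input order. This makes sessionization deterministic
   under any input permutation.
3. **Gap analysis** (`compute_gaps()`, `estimate_threshold()`): for every
   record with a same-patient predecessor, the gap in seconds. The
   inactivity threshold bounding a coherent session is a high empirical
   quantile of this distribution after removing gaps whose *later* action
   is a log-out — those carry the keep-alive spike. The later-action
   attribution matters: the artifact is a log-out stamped long after the
   last real action, so the inflated gap precedes the log-out record.
4. **Sessionization** (`assign_sessions()`): a new session starts at a
   patient's first record, at any log-in, after a gap *strictly greater*
   than the threshold, and after a log-out.
5. **Device inference** (`infer_device()`): mobile if any record carries a
   configured marker substring (default `"EpicMyChart"`) in its user agent
   or extended info; desktop if a log-in carries a non-missing agent
   without markers; unknown otherwise.
6. **Duration** (`session_duration()`): last minus first non-log-out
   timestamp, zero when fewer than two such records. Computed *before*
   duplicate removal.
7. **Classification and metrics** (`categorize()`, `dedup_actions()`,
   `session_metrics()`, `patient_metrics()`): collapse consecutive
   identical `(action type, extended info)` runs to their first record,
   then count accesses per portal function. Auxiliary actions (log-in,
   log-out, two-factor) are flagged `Miscellaneous` and excluded from
   metrics; unmapped actions are `Unclassified`, reported but never
   counted.
8. **Account status** (`summarize_accounts()`): activation time is the
   earliest `Activated` event; current status is the latest event; a
   configurable comment pattern flags accounts closed on the owner's
   death.

Validity filters mirror standard practice: a **valid session** has nonzero
effective duration (a bare log-in is not engagement), and an **active
patient** has at least two valid sessions. Patient-level counts aggregate
valid sessions only; `patient_metrics(valid_only = FALSE)` exposes the
unfiltered variant because published patient-level tables are sometimes
ambiguous about this filter.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `threshold_seconds` | 1256 s | fixed inactivity bound (~21 min), the reference value; used when estimation is skipped |
| `retention` | 0.998 | fraction of non-log-out gaps preserved when estimating the threshold |
| `mobile_markers` | `"EpicMyChart"` | user-agent substrings marking the mobile client |
| `dedup_max_interval` | `Inf` | optional cap on duplicate collapse; value matching alone decides by default |
| `deceased_pattern` | `"deceased"` | comment regex flagging death-closed accounts |

Whether a published threshold of this kind was chosen to achieve a target
retention or the retention was the consequence of the chosen threshold is
generally not recoverable; the package therefore exposes retention as the
control parameter and ships the fixed value as a default constant, without
asserting either reading.

## Numerical and tie-break choices

* **Quantile convention.** `estimate_threshold()` uses linear interpolation
  between order statistics (`stats::quantile`, type 7). The convention is
  stated because different choices shift the threshold by up to one gap
  value; any fixed convention is defensible, an unstated one is not.
* **Timestamps.** `UA_TIME` has one-second resolution and no timezone; all
  parsing uses a fixed zone (UTC) so arithmetic is pure subtraction with no
  DST discontinuities. Durations and gaps are whole seconds.
* **Boundary at the threshold.** A gap exactly equal to the threshold does
  **not** split a session (the rule splits only on strictly greater gaps).
* **Log-in after a short gap.** An explicit re-login opens a new session
  even seconds after the last action: it is a new engagement event. This
  rule is this package's choice; sources describing the approach only state
  that session starts *usually* coincide with log-ins.
* **Tie-rank.** Only "log-ins first" is externally motivated; log-outs-last
  is added so that a same-second log-out cannot precede the action it
  closes. Remaining ties keep stable input order.
* **Gap histogram.** `gap_density_profile()` bins on a log scale of
  `gap + 1` so zero-second gaps are representable; masses always sum to 1.
* **Degenerate inputs.** Empty files yield empty, well-typed outputs;
  estimation on an empty gap set fails with an instruction to supply a
  fixed threshold; sessions consisting solely of auxiliary actions are kept
  and simply marked invalid.

## The taxonomy is configuration

The two-level mapping (raw action string → action label → portal function)
ships as an editable YAML file with all 44 labels across the 8 functions
(Messaging, Visits, My record, Medical tools, Billing, Resources, Proxy,
Preferences). The raw `MYC_UA_TYPE_C` vocabulary is version- and
site-dependent and was originally established empirically per institution,
so the shipped raw-string section (e.g. `"Encounter Details"` →
Appointment details, action `"Messaging"` refined by its extended info) is
a starting point, not ground truth. Validation rejects ambiguous patterns
at load time, naming the offending entry. `Resources` is expected to carry
zero counts: its links point outside the portal and interactions are not
captured.

## What the synthetic cohort emulates — and what it does not

`simulate_cohort()` generates audit and status files in the export schema
with full ground truth, so every stage is testable without any real data.
Defaults emulate the qualitative structure reported for this kind of data:

* right-skewed sessions-per-patient counts (negative binomial, 1 + NB(1.2, 12));
* an approximately log-normal within-session gap body (log-normal(3.2, 1.1)
  seconds, rounded to whole seconds, capped at the threshold);
* predominantly single-function sessions (each session draws a goal
  function; 17% draw a second);
* ~6% abandoned log-ins (invalid sessions);
* a status mixture matching published activation shares (94% activated,
  5.3% inactivated — mostly deceased — 0.2% declined, 0.5% pending);
* both artifacts, switchable: keep-alive log-outs 1200–1320 s after last
  activity on idle desktop sessions, and mobile duplicate bursts at
  2-second spacing;
* server-session-number failure modes: numbers blanked before a cutoff
  date and numbers spanning all of a patient's sessions.

By construction, true between-session gaps exceed the threshold and every
session starts with a log-in, so with artifacts off the pipeline must
recover boundaries perfectly — that is what makes recovery scores
interpretable. `score_recovery()` projects both partitions onto
non-log-out records before comparing boundaries: a keep-alive log-out
stamped beyond the threshold correctly becomes a log-out-only session
(that split *is* the correction), and engagement boundaries are defined on
real actions.

What the generator does **not** emulate: real cohort-scale numbers
(hundreds of thousands of sessions), circadian and weekday activity
rhythms, proxy-account structure, within-patient drift in usage habits, or
a site's true raw action vocabulary. Passing recovery tests therefore
demonstrates algorithmic correctness under the stated assumptions, not
that any institution's data satisfies those assumptions — on real exports
the gap histogram and the unclassified-action report are the first things
to inspect.

## Validation design

Deterministic pieces are checked against hand-computable cases — notably a
14-row published log excerpt whose three sessions, durations (0 s, 754 s,
195 s), device ("mobile") and post-dedup counts are derived by hand from
the printed timestamps. The sessionizer is additionally checked for exact
partition agreement with an independently written naive reference on 1000
random logs with gaps straddling the threshold.

Stochastic pieces use fixed seeds and sized margins. The
threshold-estimator check draws 20 replicates of 100,000 log-normal gaps
and requires the estimate within 5% of the known 99.8th percentile; the
relative sampling error of that empirical quantile is about
`0.022 × sdlog` at this n, so the check uses sdlog 0.6, making the 5%
band a ~3.7-sigma envelope — a heavier-tailed choice would make the check
fail occasionally by sampling error alone rather than test the estimator.
End-to-end recovery runs a 200-patient cohort with all artifacts on
(~20,000 records), a size chosen to exercise every code path while keeping
the full suite fast; the emitted gap distribution is itself verified
against the configured log-normal with a Kolmogorov–Smirnov check after
de-discretizing the whole-second quantization with ±0.5 s uniform jitter.

## Known limitations

* The raw-string section of the default taxonomy will misclassify or leave
  unclassified any site vocabulary it has not seen; the data-quality
  report counts unclassified records for exactly this reason.
* Device inference is a marker heuristic on log-in metadata; a desktop
  browser spoofing a mobile agent, or agent-less log-ins, degrade it to
  `unknown` (never a wrong guess between known classes).
* Proxy use is treated as ordinary activity of the account's session;
  cross-account behavior is out of scope.
* Outpatient data has no natural per-episode cutoff; all patient-level
  metrics aggregate the full observation window.
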