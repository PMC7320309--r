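#' The portal-function vocabulary
#'
#' The eight portal functions of the two-level taxonomy, plus
#' `"Miscellaneous"` for auxiliary actions (log-ins, log-outs, two-factor
#' authentication) which are flagged but excluded from use metrics. The
#' `"Resources"` function is expected to carry zero counts: its action
#' types point to educational material hosted outside the portal, so
#' interaction is not captured.
#'
#' @param include_misc Append `"Miscellaneous"` (default FALSE).
#' @return Character vector of function names in canonical order.
#' @export
portal_functions <- function(include_misc = FALSE) {
  fns <- c("Messaging", "Visits", "My record", "Medical tools", "Billing",
           "Resources", "Proxy", "Preferences")
  if (include_misc) c(fns, "Miscellaneous") else fns
}

#' Load an action taxonomy from a YAML configuration
#'
#' The configuration is a two-level mapping: portal function -> action
#' label -> list of matchers. A matcher has an `action` pattern (matched
#' case-insensitively against the trimmed `MYC_UA_TYPE_C`), optionally an
#' `extended` pattern refining the match on `UA_EXTENDED_INFO` (one user
#' action can be instantiated via several system calls distinguished only
#' there), and optionally `substring: true` to match patterns as substrings
#' rather than whole strings. A `misc` block flags log-in, log-out, and
#' two-factor patterns, all classified `Miscellaneous`.
#'
#' Validation rejects unknown functions and ambiguous matchers (two entries
#' that would claim the same record), naming the offending entry.
#'
#' @param path Path to a YAML config; `NULL` (default) loads the shipped
#'   default, which encodes all 44 action labels of the reference taxonomy
#'   plus a site-editable raw-string section for the audit-log vocabulary.
#' @return An `action_taxonomy` object.
#' @export
load_taxonomy <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "taxonomy_default.yaml",
                        package = "portalog", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$functions)) {
    stop("taxonomy config has no 'functions' block", call. = FALSE)
  }
  known <- portal_functions(include_misc = TRUE)

  rows <- list()
  for (fn in names(cfg$functions)) {
    if (!fn %in% known) {
      stop("taxonomy entry under unknown function '", fn, "'", call. = FALSE)
    }
    labels <- cfg$functions[[fn]]
    for (lab in names(labels)) {
      matchers <- labels[[lab]]
      # a bare label with no matchers matches its own display string
      if (is.null(matchers)) matchers <- list(list(action = lab))
      for (m in matchers) {
        if (is.null(m$action)) {
          stop("matcher without 'action' under '", fn, "' / '", lab, "'",
               call. = FALSE)
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          fun = fn, label = lab,
          action = tolower(trimws(m$action)),
          extended = if (is.null(m$extended)) NA_character_ else
            tolower(trimws(m$extended)),
          substring = isTRUE(m$substring)
        )
      }
    }
  }
  entries <- dplyr::bind_rows(rows)

  misc_flags <- tibble::tibble(action = character(), flag = character())
  for (flag in names(cfg$misc %||% list())) {
    pats <- unlist(cfg$misc[[flag]])
    misc_flags <- dplyr::bind_rows(
      misc_flags,
      tibble::tibble(action = tolower(trimws(pats)), flag = flag))
    entries <- dplyr::bind_rows(entries, tibble::tibble(
      fun = "Miscellaneous", label = pats, action = tolower(trimws(pats)),
      extended = NA_character_, substring = FALSE))
  }

  dup <- duplicated(entries[, c("action", "extended", "substring")])
  if (any(dup)) {
    d <- entries[dup, ][1L, ]
    stop("ambiguous taxonomy: pattern '", d$action,
         if (!is.na(d$extended)) paste0("' / '", d$extended) else "",
         "' matched by more than one entry", call. = FALSE)
  }
  # an action-only matcher may not appear under two labels
  bare <- entries[is.na(entries$extended), ]
  if (anyDuplicated(bare$action)) {
    a <- bare$action[duplicated(bare$action)][1L]
    stop("ambiguous taxonomy: action pattern '", a,
         "' has two catch-all entries", call. = FALSE)
  }

  structure(list(entries = entries, misc_flags = misc_flags, path = path),
            class = "action_taxonomy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.action_taxonomy <- function(x, ...) {
  tab <- table(x$entries$fun[x$entries$fun != "Miscellaneous"])
  cat(sprintf("<action_taxonomy> %d labels across %d functions\n",
              dplyr::n_distinct(x$entries$label[x$entries$fun != "Miscellaneous"]),
              length(tab)))
  invisible(x)
}

#' Login/logout label sets of a taxonomy
#'
#' Convenience accessors used by the sessionizer so boundary rules and the
#' taxonomy share one vocabulary.
#'
#' @param taxonomy An `action_taxonomy`.
#' @param flag One of `"login"`, `"logout"`, `"two_factor"`.
#' @return Character vector of raw action patterns carrying the flag.
#' @export
misc_labels <- function(taxonomy, flag) {
  stopifnot(inherits(taxonomy, "action_taxonomy"))
  taxonomy$misc_flags$action[taxonomy$misc_flags$flag == flag]
}

#' Classify audit records under the taxonomy
#'
#' Matches each record's action type (refined by extended info where the
#' config demands it) and appends `action_label` and `portal_function`
#' columns. Precedence: an extended-refined match beats an action-only
#' match; whole-string matchers beat substring matchers; remaining ties go
#' to config order. Records matching nothing get `"Unclassified"` — they
#' are counted and reported downstream, never dropped.
#'
#' @param records An `audit_log`, `session_log`, or compatible tibble.
#' @param taxonomy An `action_taxonomy` from [load_taxonomy()].
#' @return `records` with `action_label` and `portal_function` appended.
#' @export
categorize <- function(records, taxonomy) {
  stopifnot(inherits(taxonomy, "action_taxonomy"))
  e <- taxonomy$entries
  e$priority <- seq_len(nrow(e))
  act <- tolower(trimws(records$action_type))
  ext <- tolower(trimws(records$extended_info))

  label <- rep(NA_character_, length(act))
  fun <- rep(NA_character_, length(act))
  rank <- rep(Inf, length(act))  # lower = better

  apply_match <- function(hit, entry, tier) {
    score <- tier * nrow(e) + entry$priority
    upd <- hit & score < rank
    label[upd] <<- entry$label
    fun[upd] <<- entry$fun
    rank[upd] <<- score
  }

  for (i in seq_len(nrow(e))) {
    entry <- e[i, ]
    if (entry$substring) {
      act_hit <- grepl(entry$action, act, fixed = TRUE)
      if (!is.na(entry$extended)) {
        hit <- act_hit & !is.na(ext) & grepl(entry$extended, ext, fixed = TRUE)
        apply_match(hit, entry, tier = 1)
      } else {
        apply_match(act_hit, entry, tier = 3)
      }
    } else {
      act_hit <- act == entry$action
      if (!is.na(entry$extended)) {
        hit <- act_hit & !is.na(ext) & ext == entry$extended
        apply_match(hit, entry, tier = 0)
      } else {
        apply_match(act_hit, entry, tier = 2)
      }
    }
  }

  out <- tibble::as_tibble(records)
  out$action_label <- ifelse(is.na(label), "Unclassified", label)
  out$portal_function <- ifelse(is.na(fun), "Unclassified", fun)
  class(out) <- class(records)
  out
}
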