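# Canonical trial-comparison schema
#
# One CSV row per treatment-vs-control comparison.  Counts may be reported as
# successes or failures; exactly one of the pair must be non-missing per arm.
# Multi-arm studies contribute one row per treatment arm, sharing study_id.
RD_SCHEMA <- c(
  "study_id", "comparison_id",
  "treat_successes", "treat_failures", "treat_total",
  "ctrl_successes", "ctrl_failures", "ctrl_total",
  "margin_pct", "analysis_population", "year",
  "reported_ci_method", "randomization_label"
)
RD_MANDATORY <- c("study_id", "comparison_id", "treat_total", "ctrl_total")

#' Orient counts to the success scale
#'
#' Trials that report failures are converted to successes by subtracting the
#' failure count from the arm total, so the risk difference always reads
#' treatment success rate minus control success rate.  The operation is
#' idempotent: success-reported counts pass through unchanged.
#'
#' @param successes,failures integer vectors, exactly one non-`NA` per entry.
#' @param total arm totals.
#' @return Integer vector of successes.
#' @export
orient_counts <- function(successes, failures, total) {
  stopifnot(length(successes) == length(total), length(failures) == length(total))
  both <- !is.na(successes) & !is.na(failures)
  if (any(both) && any(successes[both] + failures[both] != total[both]))
    stop("rows with both successes and failures must satisfy successes + failures = total")
  neither <- is.na(successes) & is.na(failures)
  if (any(neither))
    stop("rows ", paste(which(neither), collapse = ", "),
         ": neither successes nor failures given")
  out <- ifelse(is.na(successes), total - failures, successes)
  if (any(out < 0 | out > total, na.rm = TRUE))
    stop("oriented successes fall outside [0, total]")
  as.integer(out)
}

#' Select the primary analysis row for a comparison
#'
#' When a trial reports several analysis populations for the same comparison,
#' precedence is: a row flagged as the designated primary analysis, then
#' intention-to-treat, then per-protocol (co-primary ITT/PP resolves to ITT).
#'
#' @param candidates data frame of candidate rows with a column
#'   `analysis_population` in `c("ITT", "PP", "unspecified")` and optionally a
#'   logical `primary` flag.
#' @return The single selected row.
#' @export
select_primary <- function(candidates) {
  stopifnot(is.data.frame(candidates))
  if (nrow(candidates) == 0) stop("no candidate analysis rows for comparison")
  if (nrow(candidates) == 1) return(candidates)
  if (!is.null(candidates$primary) && any(candidates$primary %in% TRUE))
    return(candidates[which(candidates$primary %in% TRUE)[1], , drop = FALSE])
  pop <- candidates$analysis_population
  for (wanted in c("ITT", "PP")) {
    hit <- which(!is.na(pop) & pop == wanted)
    if (length(hit)) return(candidates[hit[1], , drop = FALSE])
  }
  candidates[1, , drop = FALSE]
}

# Validate a raw schema data frame; returns list(data = oriented df,
# rejected = data.frame(row, reason)).
.validate_trials <- function(raw) {
  missing_cols <- setdiff(RD_MANDATORY, names(raw))
  if (length(missing_cols))
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  n <- nrow(raw)
  for (col in setdiff(RD_SCHEMA, names(raw))) raw[[col]] <- rep(NA, n)
  reasons <- character(n)
  note <- function(i, why) reasons[i] <<- ifelse(reasons[i] == "", why,
                                                 paste(reasons[i], why, sep = "; "))
  num_ok <- function(v) is.na(v) | (is.finite(v) & v == round(v) & v >= 0)
  for (arm in c("treat", "ctrl")) {
    s <- suppressWarnings(as.numeric(raw[[paste0(arm, "_successes")]]))
    f <- suppressWarnings(as.numeric(raw[[paste0(arm, "_failures")]]))
    tot <- suppressWarnings(as.numeric(raw[[paste0(arm, "_total")]]))
    for (i in seq_len(n)) {
      if (is.na(tot[i]) || tot[i] < 1 || tot[i] != round(tot[i]))
        note(i, paste0(arm, "_total missing or not a positive integer"))
      else if (is.na(s[i]) && is.na(f[i]))
        note(i, paste0(arm, ": neither successes nor failures reported"))
      else {
        cnt <- if (!is.na(s[i])) s[i] else f[i]
        if (!num_ok(cnt) || is.na(cnt) || cnt > tot[i])
          note(i, paste0(arm, " count outside [0, total] or non-integer"))
      }
    }
  }
  m <- suppressWarnings(as.numeric(raw$margin_pct))
  bad_m <- !is.na(m) & (m <= 0 | m >= 100)
  for (i in which(bad_m)) note(i, "margin_pct outside (0, 100)")
  dup <- duplicated(raw$comparison_id)
  for (i in which(dup)) note(i, "duplicated comparison_id")
  keep <- reasons == ""
  dat <- raw[keep, , drop = FALSE]
  # orient to the success scale
  reported_as <- ifelse(!is.na(dat$treat_successes) & !is.na(dat$ctrl_successes),
                        "successes", "failures")
  x1 <- orient_counts(suppressWarnings(as.numeric(dat$treat_successes)),
                      suppressWarnings(as.numeric(dat$treat_failures)),
                      as.numeric(dat$treat_total))
  x2 <- orient_counts(suppressWarnings(as.numeric(dat$ctrl_successes)),
                      suppressWarnings(as.numeric(dat$ctrl_failures)),
                      as.numeric(dat$ctrl_total))
  out <- data.frame(
    study_id = as.character(dat$study_id),
    comparison_id = as.character(dat$comparison_id),
    x1 = x1, n1 = as.integer(dat$treat_total),
    x2 = x2, n2 = as.integer(dat$ctrl_total),
    outcome_reported_as = reported_as,
    margin_pct = suppressWarnings(as.numeric(dat$margin_pct)),
    analysis_population = ifelse(is.na(dat$analysis_population), "unspecified",
                                 as.character(dat$analysis_population)),
    year = suppressWarnings(as.integer(dat$year)),
    reported_ci_method = as.character(dat$reported_ci_method),
    randomization_label = as.character(dat$randomization_label),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("trial_data", "data.frame")
  list(data = out,
       rejected = data.frame(row = which(!keep), reason = reasons[!keep],
                             stringsAsFactors = FALSE))
}

#' Read a trial-comparison table from CSV
#'
#' Reads the canonical comparison schema (see `rd_schema()`), validates every
#' row, orients failure-reported counts to the success scale and returns a
#' `trial_data` data frame with columns `x1, n1` (treatment successes/total)
#' and `x2, n2` (control).  Rows violating the invariants are dropped with a
#' row-numbered warning; the rejections are attached as
#' `attr(x, "rejected")`.
#'
#' @param path CSV file path (RFC-4180, UTF-8, header row).
#' @return A `trial_data` data frame.
#' @seealso [write_results()], [generate_fixture()]
#' @export
read_trials <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  v <- .validate_trials(raw)
  if (nrow(v$rejected))
    warning(sprintf("rejected %d row(s): %s", nrow(v$rejected),
                    paste(sprintf("row %d (%s)", v$rejected$row,
                                  v$rejected$reason), collapse = "; ")))
  message(sprintf("read_trials: retained %d of %d rows", nrow(v$data), nrow(raw)))
  attr(v$data, "rejected") <- v$rejected
  v$data
}

#' Coerce an in-memory data frame to validated trial data
#'
#' Same validation and orientation as [read_trials()] without the file
#' round-trip; used by the synthetic generator so generated cohorts always
#' pass the same checks as read data.
#'
#' @param raw data frame in the canonical schema.
#' @return A `trial_data` data frame.
#' @export
as_trial_data <- function(raw) {
  v <- .validate_trials(raw)
  if (nrow(v$rejected))
    stop("invalid rows: ", paste(sprintf("row %d (%s)", v$rejected$row,
                                         v$rejected$reason), collapse = "; "))
  v$data
}

#' The canonical comparison-table column dictionary
#'
#' @return Data frame describing each column of the CSV schema.
#' @export
rd_schema <- function() {
  data.frame(
    column = RD_SCHEMA,
    required = RD_SCHEMA %in% RD_MANDATORY,
    description = c(
      "study label; shared by comparisons from one multi-arm study",
      "unique comparison label",
      "treatment-arm successes (NA if reported as failures)",
      "treatment-arm failures (NA if reported as successes)",
      "treatment-arm patients",
      "control-arm successes (NA if reported as failures)",
      "control-arm failures (NA if reported as successes)",
      "control-arm patients",
      "non-inferiority margin in percentage points, NA if unspecified",
      "ITT, PP or unspecified",
      "publication year",
      "CI method reported by the study, free text",
      "randomization ratio label, e.g. 1:1 or 2:1"),
    stringsAsFactors = FALSE
  )
}

#' Write per-comparison interval results to CSV
#'
#' One row per comparison and method, with limits and widths both on the
#' proportion scale at full precision and on the percent scale rounded to 4
#' decimal places.  Output is bit-stable across runs on identical input.
#'
#' @param results result data frame from [evaluate_trials()].
#' @param path output CSV path.
#' @return Invisibly, the data frame written.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  out <- results
  for (col in c("lower", "upper")) {
    if (!col %in% names(out)) stop("results lack column ", col)
    out[[paste0(col, "_pct")]] <- round(100 * out[[col]], 4)
  }
  if (!"width_pct" %in% names(out) && "width" %in% names(out))
    out$width_pct <- round(100 * out$width, 4)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(out)
}
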