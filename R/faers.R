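# Pharmacovigilance arm: case-report bookkeeping, 2x2 contingency tables,
# reporting odds ratio (ROR) signal detection and stratified report summaries.

report_columns <- c(
  "case_id", "version", "drug", "role", "pt", "sex", "age_years",
  "weight_kg", "reporter", "country", "year"
)

valid_roles <- c("suspect", "concomitant")
valid_sexes <- c("F", "M")
valid_reporters <- c("CN", "HP", "LW", "MD", "OT", "PH", "RN")

#' Construct a validated case-report table
#'
#' A case report is one spontaneous adverse-event record: a case identifier,
#' a report version (resubmissions increment it), the reported drug and its
#' role (primary suspect or concomitant), the adverse-event preferred term
#' (PT) and reporter demographics. Missing values are `NA`.
#'
#' @param df data.frame with columns `case_id`, `version`, `drug`, `role`,
#'   `pt`, `sex`, `age_years`, `weight_kg`, `reporter`, `country`, `year`.
#' @return the validated data.frame (character/numeric types coerced).
#' @export
#' @examples
#' case_reports(data.frame(
#'   case_id = "C1", version = 1L, drug = "haloperidol", role = "suspect",
#'   pt = "Seizure", sex = "F", age_years = 40, weight_kg = NA,
#'   reporter = "MD", country = "US", year = 2019L
#' ))
case_reports <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(report_columns, names(df))
  if (length(missing_cols)) {
    stop("case report table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- df[report_columns]
  df$case_id <- as.character(df$case_id)
  df$version <- as.integer(df$version)
  df$drug <- as.character(df$drug)
  df$role <- as.character(df$role)
  df$pt <- as.character(df$pt)
  df$sex <- as.character(df$sex)
  df$age_years <- as.numeric(df$age_years)
  df$weight_kg <- as.numeric(df$weight_kg)
  df$reporter <- as.character(df$reporter)
  df$country <- as.character(df$country)
  df$year <- as.integer(df$year)
  if (anyNA(df$case_id) || anyNA(df$version)) {
    stop("case_id and version are required on every report")
  }
  if (any(df$version < 1L)) stop("report versions must be >= 1")
  bad_role <- !is.na(df$role) & !(df$role %in% valid_roles)
  if (any(bad_role)) stop("unknown role: ", df$role[bad_role][1])
  bad_sex <- !is.na(df$sex) & !(df$sex %in% valid_sexes)
  if (any(bad_sex)) stop("unknown sex code: ", df$sex[bad_sex][1])
  bad_rep <- !is.na(df$reporter) & !(df$reporter %in% valid_reporters)
  if (any(bad_rep)) stop("unknown reporter code: ", df$reporter[bad_rep][1])
  rownames(df) <- NULL
  df
}

#' Keep one report per case: the latest version
#'
#' Spontaneous-report databases accumulate resubmissions of the same case;
#' disproportionality analysis must count each case once. The record with
#' the highest `version` is kept (ties broken by latest `year`, then first
#' occurrence). Two records claiming the same `(case_id, version)` with
#' different content are an upstream data error and are rejected.
#'
#' @param reports case-report data.frame (see [case_reports()]).
#' @return deduplicated data.frame, one row per `case_id`, ordered by
#'   `case_id`.
#' @export
deduplicate_reports <- function(reports) {
  reports <- case_reports(reports)
  if (!nrow(reports)) return(reports)
  key <- paste(reports$case_id, reports$version, sep = "\r")
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      rows <- reports[key == k, , drop = FALSE]
      if (nrow(unique(rows)) > 1L) {
        stop("conflicting duplicate version for case_id '", rows$case_id[1], "'")
      }
    }
    keep <- !duplicated(key)
    reports <- reports[keep, , drop = FALSE]
  }
  o <- order(reports$case_id, -reports$version, -reports$year,
             seq_len(nrow(reports)))
  out <- reports[o, , drop = FALSE]
  out <- out[!duplicated(out$case_id), , drop = FALSE]
  out <- out[order(out$case_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drug-by-event 2x2 contingency table
#'
#' Cross-classifies deduplicated reports by target-drug exposure and
#' target-event occurrence: `a` = target drug and target event, `b` = target
#' drug and other events, `c` = other drugs and target event, `d` = other
#' drugs and other events. When `suspect_only` is `TRUE` (the default, the
#' usual pharmacovigilance convention) a report only counts as drug-exposed
#' when the drug's role is primary suspect.
#'
#' @param reports deduplicated case-report data.frame.
#' @param target_drugs character vector of active-ingredient labels.
#' @param target_pts character vector of adverse-event preferred terms.
#' @param suspect_only count only suspect-role drug reports as exposed.
#' @return object of class `two_by_two` with fields `a`, `b`, `c`, `d` and
#'   `corrected = FALSE`.
#' @export
build_two_by_two <- function(reports, target_drugs, target_pts,
                             suspect_only = TRUE) {
  if (!length(target_drugs)) stop("target_drugs must be non-empty")
  if (!length(target_pts)) stop("target_pts must be non-empty")
  reports <- case_reports(reports)
  exposed <- reports$drug %in% target_drugs
  if (suspect_only) {
    exposed <- exposed & !is.na(reports$role) & reports$role == "suspect"
  }
  event <- reports$pt %in% target_pts
  two_by_two(
    a = sum(exposed & event),
    b = sum(exposed & !event),
    c = sum(!exposed & event),
    d = sum(!exposed & !event)
  )
}

#' Create a 2x2 table from cell counts
#'
#' @param a,b,c,d nonnegative integer cell counts (`a` = target drug with
#'   target event, `b` = target drug other events, `c` = other drugs with
#'   target event, `d` = other drugs other events).
#' @return object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("all 2x2 cells must be nonnegative counts")
  }
  structure(list(a = a, b = b, c = c, d = d, corrected = FALSE),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), nrow = 2, byrow = TRUE,
              dimnames = list(c("target drug", "other drugs"),
                              c("target event", "other events")))
  print(m)
  if (isTRUE(x$corrected)) cat("(0.5 continuity correction applied)\n")
  invisible(x)
}

#' Reporting odds ratio and signal verdict
#'
#' Computes the disproportionality statistic ROR = (a/c)/(b/d) = ad/bc with
#' Wald confidence interval
#' `exp(log(ROR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. A signal requires
#' at least `min_reports` drug-event reports (cell `a`, uncorrected) and a
#' CI lower bound strictly above 1. If any cell is zero the
#' Haldane-Anscombe correction (0.5 added to every cell) is applied first
#' and flagged via `corrected`.
#'
#' @param t `two_by_two` table.
#' @param min_reports minimum number of drug-event reports for a signal.
#' @param z normal quantile for the confidence interval (1.96 for 95%).
#' @param label free-text label carried through to the result.
#' @return object of class `signal_result` with `label`, `n_target`, cell
#'   counts, `ror`, `ci_low`, `ci_high`, `pval`, `is_signal`, `corrected`.
#' @export
#' @examples
#' ror_signal(two_by_two(10, 90, 20, 380))
ror_signal <- function(t, min_reports = 3, z = 1.96, label = "signal") {
  stopifnot(inherits(t, "two_by_two"))
  cells <- c(t$a, t$b, t$c, t$d)
  if (all(cells == 0)) stop("all-zero 2x2 table: no reports to analyse")
  n_target <- t$a
  corrected <- FALSE
  if (any(cells == 0)) {
    cells <- cells + 0.5
    corrected <- TRUE
  }
  a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
  ror <- (a * d) / (b * cc)
  se_log <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  ci_low <- exp(log(ror) - z * se_log)
  ci_high <- exp(log(ror) + z * se_log)
  structure(list(
    label = label,
    n_target = n_target,
    a = t$a, b = t$b, c = t$c, d = t$d,
    ror = ror, ci_low = ci_low, ci_high = ci_high,
    pval = p_two_sided(log(ror) / se_log),
    is_signal = (n_target >= min_reports) && (ci_low > 1),
    corrected = corrected
  ), class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("%s: ROR %.3f (95%% CI %.3f-%.3f), n=%d, signal=%s\n",
              x$label, x$ror, x$ci_low, x$ci_high, x$n_target,
              ifelse(x$is_signal, "yes", "no")))
  invisible(x)
}

weight_band <- function(w) {
  ifelse(is.na(w), NA_character_,
         ifelse(w < 50, "< 50 kg",
                ifelse(w > 100, "> 100 kg", "50-100 kg")))
}

age_band <- function(a) {
  ifelse(is.na(a), NA_character_,
         ifelse(a < 18, "< 18",
                ifelse(a < 65, "18-64.9",
                       ifelse(a <= 85, "65-85", "> 85"))))
}

characteristic_levels <- list(
  sex = c("Female", "Male"),
  weight = c("< 50 kg", "50-100 kg", "> 100 kg"),
  age = c("< 18", "18-64.9", "65-85", "> 85")
)

#' Stratified characteristics of reports with and without the target event
#'
#' Tabulates deduplicated reports by sex, weight band (<50, 50-100,
#' >100 kg), age band (<18, 18-64.9, 65-85, >85 years), reporter type,
#' year and country, split into reports without the target event, reports
#' with it, and overall. Each variable includes an explicit `Missing`
#' level so counts always sum to the column totals. Percentages use the
#' column total as denominator and are rounded half-up to one decimal.
#'
#' @param reports deduplicated case-report data.frame.
#' @param target_pts character vector of target preferred terms.
#' @return data.frame with columns `variable`, `level`,
#'   `count_no_target`, `pct_no_target`, `count_target`, `pct_target`,
#'   `count_overall`, `pct_overall`; attribute `totals` holds the three
#'   column totals.
#' @export
summarize_characteristics <- function(reports, target_pts) {
  reports <- case_reports(reports)
  is_target <- reports$pt %in% target_pts
  n_target <- sum(is_target)
  n_no <- sum(!is_target)
  n_all <- nrow(reports)

  values <- list(
    sex = ifelse(is.na(reports$sex), NA_character_,
                 ifelse(reports$sex == "F", "Female", "Male")),
    weight = weight_band(reports$weight_kg),
    age = age_band(reports$age_years),
    reporter = reports$reporter,
    year = as.character(reports$year),
    country = reports$country
  )

  pct <- function(count, total) {
    if (total == 0) return(rep(0, length(count)))
    round_half_up(100 * count / total, 1)
  }

  rows <- lapply(names(values), function(var) {
    v <- values[[var]]
    lev <- characteristic_levels[[var]]
    if (is.null(lev)) lev <- sort(unique(v[!is.na(v)]))
    lev <- c(lev, "Missing")
    v <- ifelse(is.na(v), "Missing", v)
    cn <- vapply(lev, function(l) sum(v == l & !is_target), numeric(1))
    ct <- vapply(lev, function(l) sum(v == l & is_target), numeric(1))
    data.frame(
      variable = var, level = lev,
      count_no_target = cn, pct_no_target = pct(cn, n_no),
      count_target = ct, pct_target = pct(ct, n_target),
      count_overall = cn + ct, pct_overall = pct(cn + ct, n_all),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "totals") <- c(no_target = n_no, target = n_target, overall = n_all)
  out
}
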