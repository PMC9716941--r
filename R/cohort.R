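#' PUL cohort tables
#'
#' A PUL (pregnancy of unknown location) cohort is an ordinary tibble with
#' one row per woman and the columns below. All functions in this package
#' take and return such tibbles so that pipelines compose with the pipe.
#'
#' Required columns:
#' \describe{
#'   \item{id}{unique identifier (character).}
#'   \item{age}{age in years.}
#'   \item{hcg1, hcg2}{first and second serum hCG (IU/L); strictly positive.}
#'   \item{interval_hours}{elapsed hours between the two samples; positive.}
#'   \item{bleeding, prior_ep, iud, inpatient}{logical covariate flags.}
#'   \item{pul_type}{`true_pul`, `probable_iup` or `probable_ep`.}
#'   \item{outcome}{adjudicated final outcome: `failed_pul`, `iup`, `ep`,
#'     `ppul`, `gtd` or `lost`.}
#' }
#'
#' @name pul_cohort
NULL

#' Validate a PUL cohort table
#'
#' Checks the column contract described in [pul_cohort]: unique ids,
#' strictly positive hCG values and sampling interval, and outcome /
#' PUL-type labels drawn from their enumerations. Missing covariate flags
#' (`bleeding`, `prior_ep`, `iud`, `inpatient`) are filled in as `FALSE`
#' with a warning; `hcg1`, `hcg2` and `interval_hours` may never be
#' missing.
#'
#' @param cohort A data frame with the [pul_cohort] columns.
#' @return The validated cohort as a tibble (invisibly usable in pipes).
#' @export
validate_pul_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  required <- c("id", "hcg1", "hcg2", "interval_hours", "pul_type", "outcome")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pulvalidate_data_error")
  }
  cohort$id <- as.character(cohort$id)
  if (anyDuplicated(cohort$id)) {
    abort("Cohort ids must be unique.", class = "pulvalidate_data_error")
  }
  for (col in c("hcg1", "hcg2")) {
    bad <- !is.finite(cohort[[col]]) | cohort[[col]] <= 0
    if (any(bad)) {
      abort(paste0("Invalid record(s) ", paste(cohort$id[bad], collapse = ", "),
                   ": `", col, "` must be a positive finite number."),
            class = "pulvalidate_invalid_record")
    }
  }
  bad <- !is.finite(cohort$interval_hours) | cohort$interval_hours <= 0
  if (any(bad)) {
    abort(paste0("Invalid record(s) ", paste(cohort$id[bad], collapse = ", "),
                 ": `interval_hours` must be positive."),
          class = "pulvalidate_invalid_record")
  }
  if (!all(cohort$outcome %in% pul_outcome_levels)) {
    abort(paste0("Unknown outcome label(s): ",
                 paste(setdiff(unique(cohort$outcome), pul_outcome_levels),
                       collapse = ", ")),
          class = "pulvalidate_data_error")
  }
  if (!all(cohort$pul_type %in% pul_type_levels)) {
    abort(paste0("Unknown pul_type label(s): ",
                 paste(setdiff(unique(cohort$pul_type), pul_type_levels),
                       collapse = ", ")),
          class = "pulvalidate_data_error")
  }
  for (flag in c("bleeding", "prior_ep", "iud", "inpatient")) {
    if (!flag %in% names(cohort)) {
      warn(paste0("Covariate `", flag, "` absent; defaulting to FALSE."))
      cohort[[flag]] <- FALSE
    } else if (anyNA(cohort[[flag]])) {
      warn(paste0("Missing values in `", flag, "` treated as FALSE."))
      cohort[[flag]][is.na(cohort[[flag]])] <- FALSE
    }
    cohort[[flag]] <- as.logical(cohort[[flag]])
  }
  cohort
}

#' hCG ratio: second sample over first
#'
#' The hCG ratio (hCG2 / hCG1) is the key dynamic predictor in two-sample
#' PUL triage: a ratio well below 1 suggests a resolving (failed) PUL, a
#' ratio around the 48-hour doubling expected for a viable pregnancy
#' suggests an intrauterine pregnancy, and a plateau near 1 raises concern
#' for ectopic pregnancy.
#'
#' @param hcg1,hcg2 Positive serum hCG values (IU/L), vectorised.
#' @return `hcg2 / hcg1` as a numeric vector.
#' @examples
#' hcg_ratio(500, 1000)
#' @export
hcg_ratio <- function(hcg1, hcg2) {
  if (any(!is.finite(hcg1) | hcg1 <= 0)) {
    abort("Invalid record: `hcg1` must be positive.",
          class = "pulvalidate_invalid_record")
  }
  if (any(!is.finite(hcg2) | hcg2 <= 0)) {
    abort("Invalid record: `hcg2` must be positive.",
          class = "pulvalidate_invalid_record")
  }
  hcg2 / hcg1
}

#' Add the hCG ratio column to a cohort
#'
#' @param cohort A [pul_cohort] tibble.
#' @return The cohort with an added `hcg_ratio` column.
#' @export
add_hcg_ratio <- function(cohort) {
  dplyr::mutate(tibble::as_tibble(cohort),
                hcg_ratio = hcg_ratio(.data$hcg1, .data$hcg2))
}

#' Bin the sampling interval between two hCG measurements
#'
#' Bins use inclusive integer-hour boundaries: `lt24` (< 24 h), `24-39`,
#' `40-56` (the clinical 48 +/- 8 h window), `57-72`, and `gt72` (> 72 h).
#'
#' @param interval_hours Positive hours between samples, vectorised.
#' @return A factor with levels `lt24`, `24-39`, `40-56`, `57-72`, `gt72`.
#' @examples
#' interval_bin(c(20, 48, 72, 73))
#' @export
interval_bin <- function(interval_hours) {
  if (any(!is.finite(interval_hours) | interval_hours <= 0)) {
    abort("`interval_hours` must be positive.",
          class = "pulvalidate_invalid_record")
  }
  out <- dplyr::case_when(
    interval_hours < 24 ~ "lt24",
    interval_hours < 40 ~ "24-39",
    interval_hours <= 56 ~ "40-56",
    interval_hours <= 72 ~ "57-72",
    TRUE ~ "gt72"
  )
  factor(out, levels = interval_bin_levels)
}

#' Apply cohort inclusion criteria
#'
#' Retains records whose hCG sampling interval lies within
#' `[min_hours, max_hours]` (both boundaries inclusive) and whose outcome is
#' analysable; records with gestational trophoblastic disease (`gtd`) or
#' lost to follow-up (`lost`) are excluded by default. Setting
#' `min_hours = 0, max_hours = Inf` keeps every sampling interval, which is
#' how a sensitivity-analysis cohort ignoring the interval window is built.
#'
#' A per-record disposition log is attached as the `"exclusion_log"`
#' attribute (see [exclusion_log()]). When a record fails several criteria
#' it is logged under the first that applies, in the order interval window,
#' then GTD, then lost to follow-up, so the dispositions partition the
#' input.
#'
#' @param cohort A [pul_cohort] tibble.
#' @param min_hours,max_hours Inclusive interval window in hours.
#' @param exclude_gtd,exclude_lost Drop `gtd` / `lost` outcomes?
#' @return The retained cohort, with the exclusion log attached.
#' @export
apply_inclusion <- function(cohort, min_hours = 24, max_hours = 72,
                            exclude_gtd = TRUE, exclude_lost = TRUE) {
  cohort <- validate_pul_cohort(suppressWarnings(tibble::as_tibble(cohort)))
  disposition <- rep("retained", nrow(cohort))
  out_of_window <- cohort$interval_hours < min_hours |
    cohort$interval_hours > max_hours
  disposition[out_of_window] <- "excluded_interval"
  if (exclude_gtd) {
    disposition[disposition == "retained" & cohort$outcome == "gtd"] <-
      "excluded_gtd"
  }
  if (exclude_lost) {
    disposition[disposition == "retained" & cohort$outcome == "lost"] <-
      "excluded_lost"
  }
  log <- tibble::tibble(id = cohort$id, disposition = disposition)
  categories <- c("retained", "excluded_interval", "excluded_gtd",
                  "excluded_lost")
  tallies <- vapply(categories, function(d) sum(disposition == d), integer(1))
  counts <- tibble::tibble(disposition = categories, n = unname(tallies))
  retained <- cohort[disposition == "retained", , drop = FALSE]
  if (nrow(retained) == 0) {
    warn("No records retained after applying inclusion criteria.")
  }
  attr(retained, "exclusion_log") <-
    structure(list(records = log, counts = counts, n_input = nrow(cohort)),
              class = "pul_exclusion_log")
  retained
}

#' Retrieve the exclusion log from a filtered cohort
#'
#' @param cohort A cohort returned by [apply_inclusion()].
#' @return A `pul_exclusion_log`: list with `records` (id, disposition),
#'   `counts` (per-disposition tally) and `n_input`.
#' @export
exclusion_log <- function(cohort) {
  log <- attr(cohort, "exclusion_log")
  if (is.null(log)) {
    abort("No exclusion log attached; run `apply_inclusion()` first.",
          class = "pulvalidate_argument_error")
  }
  log
}

#' @export
print.pul_exclusion_log <- function(x, ...) {
  cat("PUL cohort exclusion log (", x$n_input, " records in)\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pul_exclusion_log <- function(x, ...) x$counts

#' Serialise an exclusion log to JSON
#'
#' @param log A `pul_exclusion_log`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(log, path) {
  stopifnot(inherits(log, "pul_exclusion_log"))
  jsonlite::write_json(
    list(n_input = log$n_input,
         counts = as.list(stats::setNames(log$counts$n, log$counts$disposition)),
         records = log$records),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Dichotomise PUL outcomes into ectopic-positive and negative
#'
#' Ectopic pregnancy (`ep`) and persisting PUL (`ppul`) count as positive;
#' failed PUL and intrauterine pregnancy count as negative. Persisting PUL
#' are managed as ectopics, hence grouped with them. `gtd` and `lost`
#' records must be excluded before analysis and raise an error here.
#'
#' @param outcome Character vector of outcome labels.
#' @return Logical vector: `TRUE` for EP/PPUL.
#' @examples
#' dichotomize_outcome(c("ep", "ppul", "iup", "failed_pul"))
#' @export
dichotomize_outcome <- function(outcome) {
  bad <- !outcome %in% pul_analysis_outcomes
  if (any(bad)) {
    abort(paste0("Outcome(s) not analysable (exclude before analysis): ",
                 paste(unique(outcome[bad]), collapse = ", ")),
          class = "pulvalidate_data_error")
  }
  outcome %in% c("ep", "ppul")
}

#' Read a PUL cohort from CSV
#'
#' The CSV must carry a header with the [pul_cohort] columns. The sampling
#' interval may be given either as an `interval_hours` column or as two
#' ISO-8601 datetime columns `t1` and `t2` (the interval is then computed
#' in hours); `interval_hours` takes precedence when both are present.
#'
#' @param path CSV file path.
#' @return A validated [pul_cohort] tibble.
#' @export
read_pul_cohort <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"interval_hours" %in% names(raw)) {
    if (all(c("t1", "t2") %in% names(raw))) {
      t1 <- as.POSIXct(raw$t1, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
      t2 <- as.POSIXct(raw$t2, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
      if (anyNA(t1) || anyNA(t2)) {
        abort("Could not parse `t1`/`t2` as ISO-8601 datetimes.",
              class = "pulvalidate_data_error")
      }
      raw$interval_hours <- as.numeric(difftime(t2, t1, units = "hours"))
    } else {
      abort("CSV needs either `interval_hours` or both `t1` and `t2`.",
            class = "pulvalidate_data_error")
    }
  }
  raw$t1 <- NULL
  raw$t2 <- NULL
  validate_pul_cohort(raw)
}

#' Write a PUL cohort to CSV
#'
#' @param cohort A [pul_cohort] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pul_cohort <- function(cohort, path) {
  keep <- c("id", "age", "hcg1", "hcg2", "interval_hours", "bleeding",
            "prior_ep", "iud", "inpatient", "pul_type", "outcome")
  readr::write_csv(dplyr::select(tibble::as_tibble(cohort),
                                 dplyr::any_of(keep)), path, progress = FALSE)
  invisible(path)
}
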