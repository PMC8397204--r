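# Cohort CSV schema: column classes. Header names are exact and
# case-sensitive; booleans serialize as 0/1; missing values as empty
# cells.
cohort_schema <- function() {
  list(
    required = c("record_id", "ga_weeks", "pv_mm", "av_mm"),
    required_either = list(aao = c("aao_z", "aao_mm"),
                           isthmus_3vt = c("isthmus_3vt_z",
                                           "isthmus_3vt_mm")),
    character = c("record_id", "arch_flow", "fo_flow", "onset_group"),
    logical = c("plsvc", "rfop", "diffuse_arch_hypoplasia",
                "contraductal_shelf", "vsd",
                "diastolic_flow_persistence", "outcome_coao",
                "chromosomal_abnormality", "growth_restriction",
                "associated_major_chd", "extrinsic_compression",
                "lost_follow_up"),
    numeric = c("ga_weeks", "aao_z", "isthmus_3vt_z", "pv_mm", "av_mm",
                "tv_mm", "mv_mm", "mpa_mm", "aao_mm", "isthmus_3vt_mm",
                "isthmus_sagittal_mm", "da_3vt_mm", "mv_z", "tv_z",
                "transverse_arch_z", "rv_lv_ratio",
                "isthmus_ductal_angle_deg", "csa_index",
                "transaortic_peak_velocity", "predicted_probability"))
}

#' Read a cohort CSV
#'
#' Reads and type-checks a per-fetus cohort table. Required columns:
#' `record_id`, `ga_weeks`, `pv_mm`, `av_mm`, and either `aao_z` or
#' `aao_mm`, and either `isthmus_3vt_z` or `isthmus_3vt_mm`. Gestational
#' age may be decimal weeks or `"W+D"` strings. Boolean columns are
#' encoded 0/1; empty cells are missing. Rows violating record-level
#' invariants (non-positive diameters, GA outside `[11, 42]`) are
#' dropped and reported in the `"row_errors"` attribute (a data.frame
#' with `row` and `message`) rather than aborting the load.
#'
#' @param path CSV file path.
#' @return A typed cohort data.frame; inspect `attr(x, "row_errors")`.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  sch <- cohort_schema()
  missing_cols <- setdiff(sch$required, names(raw))
  for (alt in sch$required_either) {
    if (!any(alt %in% names(raw))) {
      missing_cols <- c(missing_cols, paste(alt, collapse = " or "))
    }
  }
  if (length(missing_cols) > 0) {
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = "; "), call. = FALSE)
  }
  out <- raw
  for (col in names(out)) {
    v <- out[[col]]
    v[v == ""] <- NA
    if (col == "ga_weeks") {
      out[[col]] <- parse_ga(v)
    } else if (col %in% sch$logical) {
      if (!all(v %in% c("0", "1", NA))) {
        stop("boolean column '", col, "' must be encoded 0/1",
             call. = FALSE)
      }
      out[[col]] <- v == "1"
    } else if (col %in% sch$numeric) {
      out[[col]] <- as.numeric(v)
    } else {
      out[[col]] <- v
    }
  }
  errors <- data.frame(row = integer(), message = character())
  bad <- rep(FALSE, nrow(out))
  note <- function(rows, msg) {
    for (r in which(rows)) {
      errors <<- rbind(errors, data.frame(row = r, message = msg))
    }
    bad <<- bad | rows
  }
  note(is.na(out$ga_weeks) | out$ga_weeks < 11 | out$ga_weeks > 42,
       "ga_weeks missing or outside [11, 42]")
  for (col in intersect(sch$numeric, names(out))) {
    if (grepl("_mm$", col)) {
      note(!is.na(out[[col]]) & out[[col]] <= 0,
           paste0("non-positive diameter ", col))
    }
  }
  result <- out[!bad, , drop = FALSE]
  rownames(result) <- NULL
  attr(result, "row_errors") <- errors
  result
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: booleans as 0/1, missing values as empty
#' cells, probabilities at 6 decimal places. `read_cohort()` on the
#' output reproduces the input field-by-field.
#'
#' @param cohort Cohort data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  sch <- cohort_schema()
  for (col in names(out)) {
    if (is.logical(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), NA_integer_,
                           as.integer(out[[col]]))
    } else if (col == "predicted_probability") {
      out[[col]] <- round(out[[col]], 6)
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read / write a generator configuration as JSON
#'
#' @param path File path.
#' @return `read_cohort_config()`: a [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  ga <- function(g) list(mean = g$mean, sd = g$sd,
                         bounds = unlist(g$bounds))
  cohort_config(
    n = d$n, prevalence = d$prevalence,
    early_fraction = unlist(d$early_fraction),
    ga_early = ga(d$ga_early), ga_late = ga(d$ga_late),
    z_params = d$z_params, pvav_params = d$pvav_params,
    av_baseline = unlist(d$av_baseline),
    qualitative_probs = lapply(d$qualitative_probs, function(f)
      lapply(f, unlist)),
    extras = d$extras,
    seed = if (!is.null(d$seed)) d$seed else 1L)
}

#' @rdname read_cohort_config
#' @param config A `"cohort_config"`.
#' @export
write_cohort_config <- function(config, path) {
  doc <- unclass(config)
  # named numeric vectors must serialize as JSON objects, not arrays
  doc$early_fraction <- as.list(doc$early_fraction)
  doc$qualitative_probs <- lapply(doc$qualitative_probs, function(f)
    lapply(f, as.list))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
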