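#' A polynomial z-score reference for a cardiac dimension
#'
#' Published fetal cardiac z-score models are almost universally of the
#' form z = (t(y) - mean(x)) / sd(x), with t the identity or natural log
#' and mean/sd polynomials in a predictor (gestational age or femur
#' length). This constructor captures that family; coefficients are
#' supplied by the user (or loaded with [read_zscore_references()]), so
#' any published equation set can be plugged in. The package ships only
#' clearly-labelled synthetic fixture coefficients for testing
#' (`extdata/zrefs_synthetic.json`) — it asserts no published equation.
#'
#' @param reference_id Free-text identifier of the source equations.
#' @param structure One of `"aao"`, `"isthmus_3vt"`, `"isthmus_sagittal"`,
#'   `"pv"`, `"av"`, `"tv"`, `"mv"`, `"mpa"`, `"da"`.
#' @param mean_coefficients,sd_coefficients Numeric polynomial
#'   coefficients, intercept first, for the mean and SD of the
#'   (transformed) measurement as functions of the predictor.
#' @param range Length-2 numeric: the predictor range over which the
#'   reference is declared valid (enforced by [compute_z()]).
#' @param predictor `"ga_weeks"` (default) or `"femur_length_mm"`.
#' @param transform `"identity"` (default) or `"log"` (natural log of the
#'   measurement in mm).
#' @return An object of class `"zscore_reference"`.
#' @export
zscore_reference <- function(reference_id, structure, mean_coefficients,
                             sd_coefficients, range,
                             predictor = c("ga_weeks", "femur_length_mm"),
                             transform = c("identity", "log")) {
  structure_id <- match.arg(structure,
                            c("aao", "isthmus_3vt", "isthmus_sagittal",
                              "pv", "av", "tv", "mv", "mpa", "da"))
  predictor <- match.arg(predictor)
  transform <- match.arg(transform)
  stopifnot(is.numeric(mean_coefficients), length(mean_coefficients) >= 1,
            is.numeric(sd_coefficients), length(sd_coefficients) >= 1,
            is.numeric(range), length(range) == 2L, range[1] < range[2])
  ref <- structure(
    list(reference_id = as.character(reference_id),
         structure = structure_id, predictor = predictor,
         transform = transform,
         mean_coefficients = as.numeric(mean_coefficients),
         sd_coefficients = as.numeric(sd_coefficients),
         range = as.numeric(range)),
    class = "zscore_reference")
  # SD polynomial must be strictly positive over the declared range
  grid <- seq(range[1], range[2], length.out = 101)
  if (any(eval_poly(ref$sd_coefficients, grid) <= 0)) {
    stop("SD polynomial is not strictly positive over the declared range",
         call. = FALSE)
  }
  ref
}

eval_poly <- function(coefs, x) {
  out <- rep(0, length(x))
  for (i in rev(seq_along(coefs))) out <- out * x + coefs[i]
  out
}

#' Compute a z-score from a raw measurement
#'
#' z = (t(value) - mean_poly(predictor)) / sd_poly(predictor), with t
#' identity or natural log according to the reference.
#'
#' @param value Measurement in mm, strictly positive.
#' @param predictor_value Predictor (weeks or mm); must lie inside the
#'   reference's declared range.
#' @param ref A [zscore_reference()].
#' @return z-score in reference SD units.
#' @export
compute_z <- function(value, predictor_value, ref) {
  stopifnot(inherits(ref, "zscore_reference"))
  if (any(value <= 0)) {
    stop("measurement must be strictly positive (got ",
         paste(value[value <= 0], collapse = ", "), " mm)", call. = FALSE)
  }
  if (any(predictor_value < ref$range[1] | predictor_value > ref$range[2])) {
    stop(sprintf(
      "predictor outside the declared range [%g, %g] of reference '%s'",
      ref$range[1], ref$range[2], ref$reference_id), call. = FALSE)
  }
  t_val <- if (ref$transform == "log") log(value) else value
  (t_val - eval_poly(ref$mean_coefficients, predictor_value)) /
    eval_poly(ref$sd_coefficients, predictor_value)
}

#' Invert a z-score back to a measurement
#'
#' @inheritParams compute_z
#' @param z z-score.
#' @return Measurement in mm such that `compute_z()` recovers `z`.
#' @export
invert_z <- function(z, predictor_value, ref) {
  stopifnot(inherits(ref, "zscore_reference"))
  t_val <- eval_poly(ref$mean_coefficients, predictor_value) +
    z * eval_poly(ref$sd_coefficients, predictor_value)
  if (ref$transform == "log") exp(t_val) else t_val
}

#' Fill missing exam z-scores from raw diameters
#'
#' Populates `aao_z` and `isthmus_3vt_z` from `aao_mm` /
#' `isthmus_3vt_mm` and the gestational age, using the matching
#' reference. An explicitly provided z-score is never overwritten.
#'
#' @param exam A [fetal_echo_exam()].
#' @param refs A list of [zscore_reference()]s (any order; matched by
#'   `structure`).
#' @return The exam with z fields filled where possible.
#' @export
attach_zscores <- function(exam, refs) {
  stopifnot(inherits(exam, "fetal_echo_exam"), is.list(refs))
  by_structure <- stats::setNames(
    refs, vapply(refs, `[[`, character(1), "structure"))
  fill <- function(z_field, mm_field, structure_id) {
    if (!is.na(exam[[z_field]]) || is.na(exam[[mm_field]])) return()
    ref <- by_structure[[structure_id]]
    if (is.null(ref)) {
      stop("no z-score reference supplied for structure '", structure_id,
           "' (needed to convert ", mm_field, ")", call. = FALSE)
    }
    exam[[z_field]] <<- compute_z(exam[[mm_field]], exam$ga_weeks, ref)
  }
  fill("aao_z", "aao_mm", "aao")
  fill("isthmus_3vt_z", "isthmus_3vt_mm", "isthmus_3vt")
  exam
}

#' Read / write z-score reference sets as JSON
#'
#' Each element of the JSON array has keys `reference_id`, `structure`,
#' `predictor`, `transform`, `range` (`[lo, hi]`), `mean` and `sd`
#' (polynomial coefficients, intercept first).
#'
#' @param path File path.
#' @return `read_zscore_references()`: a list of [zscore_reference()]s.
#' @export
read_zscore_references <- function(path) {
  docs <- jsonlite::read_json(path)
  lapply(docs, function(d) {
    zscore_reference(d$reference_id, d$structure,
                     unlist(d$mean), unlist(d$sd), unlist(d$range),
                     predictor = d$predictor, transform = d$transform)
  })
}

#' @rdname read_zscore_references
#' @param refs List of [zscore_reference()]s.
#' @export
write_zscore_references <- function(refs, path) {
  docs <- lapply(refs, function(r) {
    list(reference_id = r$reference_id, structure = r$structure,
         predictor = r$predictor, transform = r$transform,
         range = r$range, mean = r$mean_coefficients,
         sd = r$sd_coefficients)
  })
  jsonlite::write_json(docs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Synthetic z-score references used by the cohort generator
#'
#' GA-linear mean and constant SD on the log-millimetre scale —
#' deliberately simple synthetic fixtures (not published equations) that
#' make raw diameters and z-scores mutually consistent in simulated
#' cohorts and tests; the log transform keeps back-filled diameters
#' strictly positive at any z.
#'
#' @return A list of [zscore_reference()]s for `aao` and `isthmus_3vt`.
#' @export
synthetic_zscore_references <- function() {
  list(
    zscore_reference("synthetic-loglinear-v1", "aao",
                     mean_coefficients = c(0.26, 0.051),
                     sd_coefficients = 0.13, range = c(14, 42),
                     transform = "log"),
    zscore_reference("synthetic-loglinear-v1", "isthmus_3vt",
                     mean_coefficients = c(-0.13, 0.046),
                     sd_coefficients = 0.15, range = c(14, 42),
                     transform = "log"))
}
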