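#' A fetal echocardiographic examination record
#'
#' Holds the measurements of a single diagnostic examination of a fetus
#' referred for cardiac asymmetry with right dominance: gestational age,
#' z-scores (or raw diameters plus a reference, see [attach_zscores()]),
#' valve and vessel diameters, and qualitative / functional findings.
#' Only the fields the likelihood-ratio score consumes (`ga_weeks`,
#' `aao_z`, `isthmus_3vt_z`, `pv_mm` + `av_mm`) are ever required;
#' everything else is optional and exists for the comparator rules and
#' group comparisons.
#'
#' @param ga_weeks Gestational age at the examination, decimal weeks
#'   (weeks + days/7), in `[11, 42]`. `"W+D"` strings ("24+3") are
#'   accepted and normalized.
#' @param aao_z,isthmus_3vt_z z-scores of the ascending aorta and of the
#'   aortic isthmus in the three-vessels-and-trachea view.
#' @param pv_mm,av_mm Pulmonary and aortic valve diameters, mm.
#' @param tv_mm,mv_mm,mpa_mm,aao_mm,isthmus_3vt_mm,isthmus_sagittal_mm,da_3vt_mm
#'   Optional additional diameters, mm; all must be strictly positive when
#'   present.
#' @param mv_z,tv_z,transverse_arch_z Optional additional z-scores used by
#'   comparator rules.
#' @param rv_lv_ratio,isthmus_ductal_angle_deg,csa_index Optional derived
#'   quantities used by comparator rules (right/left ventricular width
#'   ratio; isthmus-ductal angle in degrees; carotid-subclavian artery
#'   index).
#' @param plsvc,rfop,diffuse_arch_hypoplasia,contraductal_shelf,vsd,diastolic_flow_persistence
#'   Optional logical qualitative findings (persistent left superior vena
#'   cava, redundant foramen ovale flap, etc.).
#' @param arch_flow Optional, one of `"antegrade"`, `"mixed"`,
#'   `"reversed"`.
#' @param fo_flow Optional, one of `"right_to_left"`, `"left_to_right"`,
#'   `"bidirectional"`.
#' @param transaortic_peak_velocity Optional peak velocity, cm/s.
#'
#' @return An object of class `"fetal_echo_exam"` (a named list; absent
#'   optional fields are `NA`).
#' @export
fetal_echo_exam <- function(ga_weeks,
                            aao_z = NA_real_, isthmus_3vt_z = NA_real_,
                            pv_mm = NA_real_, av_mm = NA_real_,
                            tv_mm = NA_real_, mv_mm = NA_real_,
                            mpa_mm = NA_real_, aao_mm = NA_real_,
                            isthmus_3vt_mm = NA_real_,
                            isthmus_sagittal_mm = NA_real_,
                            da_3vt_mm = NA_real_,
                            mv_z = NA_real_, tv_z = NA_real_,
                            transverse_arch_z = NA_real_,
                            rv_lv_ratio = NA_real_,
                            isthmus_ductal_angle_deg = NA_real_,
                            csa_index = NA_real_,
                            plsvc = NA, rfop = NA,
                            diffuse_arch_hypoplasia = NA,
                            contraductal_shelf = NA, vsd = NA,
                            diastolic_flow_persistence = NA,
                            arch_flow = NA_character_,
                            fo_flow = NA_character_,
                            transaortic_peak_velocity = NA_real_) {
  ga_weeks <- parse_ga(ga_weeks)
  if (is.na(ga_weeks) || ga_weeks < 11 || ga_weeks > 42) {
    stop("ga_weeks must lie in [11, 42] weeks", call. = FALSE)
  }
  diam <- list(pv_mm = pv_mm, av_mm = av_mm, tv_mm = tv_mm, mv_mm = mv_mm,
               mpa_mm = mpa_mm, aao_mm = aao_mm,
               isthmus_3vt_mm = isthmus_3vt_mm,
               isthmus_sagittal_mm = isthmus_sagittal_mm,
               da_3vt_mm = da_3vt_mm)
  for (nm in names(diam)) {
    v <- diam[[nm]]
    if (!is.na(v) && v <= 0) {
      stop("diameter ", nm, " must be strictly positive", call. = FALSE)
    }
  }
  if (!is.na(arch_flow)) {
    arch_flow <- match.arg(arch_flow, c("antegrade", "mixed", "reversed"))
  }
  if (!is.na(fo_flow)) {
    fo_flow <- match.arg(fo_flow,
                         c("right_to_left", "left_to_right",
                           "bidirectional"))
  }
  structure(
    list(ga_weeks = ga_weeks, aao_z = as.numeric(aao_z),
         isthmus_3vt_z = as.numeric(isthmus_3vt_z),
         pv_mm = as.numeric(pv_mm), av_mm = as.numeric(av_mm),
         tv_mm = as.numeric(tv_mm), mv_mm = as.numeric(mv_mm),
         mpa_mm = as.numeric(mpa_mm), aao_mm = as.numeric(aao_mm),
         isthmus_3vt_mm = as.numeric(isthmus_3vt_mm),
         isthmus_sagittal_mm = as.numeric(isthmus_sagittal_mm),
         da_3vt_mm = as.numeric(da_3vt_mm),
         mv_z = as.numeric(mv_z), tv_z = as.numeric(tv_z),
         transverse_arch_z = as.numeric(transverse_arch_z),
         rv_lv_ratio = as.numeric(rv_lv_ratio),
         isthmus_ductal_angle_deg = as.numeric(isthmus_ductal_angle_deg),
         csa_index = as.numeric(csa_index),
         plsvc = as.logical(plsvc), rfop = as.logical(rfop),
         diffuse_arch_hypoplasia = as.logical(diffuse_arch_hypoplasia),
         contraductal_shelf = as.logical(contraductal_shelf),
         vsd = as.logical(vsd),
         diastolic_flow_persistence =
           as.logical(diastolic_flow_persistence),
         arch_flow = arch_flow, fo_flow = fo_flow,
         transaortic_peak_velocity =
           as.numeric(transaortic_peak_velocity)),
    class = "fetal_echo_exam")
}

#' Parse gestational age
#'
#' Accepts decimal weeks (`24.43`) or obstetric `"W+D"` strings
#' (`"24+3"`, i.e. 24 weeks 3 days), returning decimal weeks.
#'
#' @param x Numeric or character scalar/vector.
#' @return Numeric decimal weeks.
#' @export
parse_ga <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  vapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_real_)
    if (grepl("^\\s*\\d+\\s*\\+\\s*\\d+\\s*$", s)) {
      parts <- as.numeric(strsplit(s, "\\+")[[1]])
      if (parts[2] > 6) {
        stop("days component of 'W+D' gestational age must be 0-6: ", s,
             call. = FALSE)
      }
      parts[1] + parts[2] / 7
    } else {
      v <- suppressWarnings(as.numeric(s))
      if (is.na(v)) stop("cannot parse gestational age: ", s, call. = FALSE)
      v
    }
  }, numeric(1), USE.NAMES = FALSE)
}

#' Right/left cardiac structure ratios
#'
#' Plain quotients of the paired right- and left-sided measurements:
#' TV/MV, PV/AV, MPA/AAo and isthmus(3VT)/ductus. A ratio is only present
#' in the result when both operands are available and the denominator is
#' positive.
#'
#' @param exam A [fetal_echo_exam()].
#' @return Named list with any of `tv_mv`, `pv_av`, `mpa_aao`,
#'   `isthmus_da`; absent ratios are omitted.
#' @examples
#' cardiac_ratios(fetal_echo_exam(30, pv_mm = 6.4, av_mm = 4))$pv_av
#' @export
cardiac_ratios <- function(exam) {
  stopifnot(inherits(exam, "fetal_echo_exam"))
  pairs <- list(tv_mv = c("tv_mm", "mv_mm"),
                pv_av = c("pv_mm", "av_mm"),
                mpa_aao = c("mpa_mm", "aao_mm"),
                isthmus_da = c("isthmus_3vt_mm", "da_3vt_mm"))
  out <- list()
  for (nm in names(pairs)) {
    num <- exam[[pairs[[nm]][1]]]
    den <- exam[[pairs[[nm]][2]]]
    if (!is.na(num) && !is.na(den) && den > 0) out[[nm]] <- num / den
  }
  out
}

#' Resolve gestational dating between LMP and first-trimester ultrasound
#'
#' When the last menstrual period (LMP) is unreliable the crown-rump
#' length (CRL) dating is used; even with a reliable LMP, a discordance of
#' strictly more than 7 days between the two datings defers to the CRL.
#'
#' @param lmp_ga,crl_ga Gestational age in weeks by LMP and by CRL at the
#'   dating scan.
#' @param lmp_reliable Logical: is the LMP considered reliable?
#' @return Decimal weeks to use for dating.
#' @examples
#' resolve_gestational_dating(12, 13.2, TRUE)  # 13.2: > 7 day discordance
#' resolve_gestational_dating(12, 13.0, TRUE)  # 12: exactly 7 days, kept
#' @export
resolve_gestational_dating <- function(lmp_ga, crl_ga, lmp_reliable) {
  stopifnot(is.numeric(lmp_ga), is.numeric(crl_ga),
            is.logical(lmp_reliable))
  if (!lmp_reliable) return(crl_ga)
  if (abs(lmp_ga - crl_ga) > 7 / 7) crl_ga else lmp_ga
}

#' @export
print.fetal_echo_exam <- function(x, ...) {
  cat(sprintf("Fetal echo exam at %.1f weeks\n", x$ga_weeks))
  flds <- c("aao_z", "isthmus_3vt_z", "pv_mm", "av_mm")
  for (f in flds) cat(sprintf("  %-14s %s\n", f,
                              ifelse(is.na(x[[f]]), "-",
                                     format(x[[f]]))))
  invisible(x)
}
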