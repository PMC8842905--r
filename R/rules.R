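# Rule-based diagnostic layer: maps a measurement vector onto the 21-template
# (CMT) criteria via skeletal class (ANB), vertical type (MP/SN) and the
# special features (lip-to-E-line protrusion, deep overjet, anterior
# crossbite severity, incisor linguoclination, open bite).

#' Default clinical thresholds for the CMT rule engine
#'
#' The skeletal-class ANB interval and MP/SN vertical bands are not part of
#' the template criteria themselves; the defaults follow widely used
#' Chinese-population norms (Class I: ANB in \[0, 4.7\] degrees; average
#' angle: MP/SN in \[27, 37\] degrees) and every report prints them. Lip,
#' overjet and overbite thresholds are the template criteria values; the
#' linguoclination cutoff (U1/SN < 90 degrees) is a documented default.
#'
#' @return named list of thresholds (degrees / mm).
#' @export
default_thresholds <- function() {
  list(
    anb_class1 = c(0.0, 4.7),        # degrees, closed interval
    mpsn_low = 27.0, mpsn_high = 37.0, # degrees, closed middle band
    lip_straight_mm = 1.0, lip_straight_sum_mm = 2.0,     # class I split
    lip_classII_mm = 2.5, lip_classII_sum_mm = 4.0,       # class II split
    deep_overjet_mm = 8.0,
    class3_mild_low = -3.0,          # average/high angle: overjet in (-3, 0)
    class3_mild_low_lowangle = -2.0, # low angle: overjet in (-2, 0)
    openbite_overbite_mm = 0.0,
    linguoclination_u1sn_deg = 90.0
  )
}

#' Skeletal class from the ANB angle
#'
#' Class I when ANB lies inside the configured closed interval, II above it,
#' III below it.
#'
#' @param anb ANB angle in degrees (finite).
#' @param thresholds see [default_thresholds()].
#' @return `"I"`, `"II"` or `"III"` (vectorized).
#' @export
classify_skeletal <- function(anb, thresholds = default_thresholds()) {
  lo <- thresholds$anb_class1[1]
  hi <- thresholds$anb_class1[2]
  ifelse(anb > hi, "II", ifelse(anb < lo, "III", "I"))
}

#' Vertical (mandibular-plane) type from MP/SN
#'
#' `"average"` inside the closed band, `"low"` below, `"high"` above.
#'
#' @param mpsn MP/SN angle in degrees.
#' @param thresholds see [default_thresholds()].
#' @return `"low"`, `"average"` or `"high"` (vectorized).
#' @export
classify_angle <- function(mpsn, thresholds = default_thresholds()) {
  ifelse(mpsn > thresholds$mpsn_high, "high",
         ifelse(mpsn < thresholds$mpsn_low, "low", "average"))
}

# Precedence for the primary template when several criteria match, applied
# within the skeletal class: open bite first, then deep overjet / severe
# class-III overjet, then linguoclination, then the lip-protrusion split and
# mild class-III overjet.
cmt_precedence <- function() {
  c(15L, 21L, 6L, 9L, 10L, 11L, 18L, 19L, 20L, 14L, 16L, 17L,
    1L, 2L, 3L, 4L, 5L, 7L, 8L, 12L, 13L)
}

required_rule_measurements <- function() {
  c("ANB", "MP/SN", "overjet", "overbite", "U1/SN", "UL-EP", "LL-EP")
}

#' Diagnose a case against the 21 CMT criteria
#'
#' Evaluates all 21 template criteria on a measurement vector. The lip split
#' is made exhaustive and exclusive within each skeletal class: protrusion =
#' (both lips beyond the threshold) OR (their sum beyond the sum threshold),
#' straight otherwise. `matched` lists every satisfied template;
#' `primary_cmt` applies the documented precedence (open bite before deep
#' overjet / severe class-III overjet before linguoclination before the lip
#' split). A case matching no template is `"unclassed"`.
#'
#' @param measurements named numeric vector (or one-row data.frame) holding
#'   at least ANB, MP/SN, overjet, overbite, U1/SN, UL-EP (Ls-E) and LL-EP
#'   (Li-E).
#' @param thresholds see [default_thresholds()].
#' @param case_id optional identifier carried into the result.
#' @return a `ceph_diagnosis` list: `case_id`, `skeletal_class`,
#'   `angle_type`, `matched` (integer CMT ids), `primary_cmt` (integer or
#'   `"unclassed"`), `trace` (named logical vector of all 21 criteria), and
#'   the `thresholds` used.
#' @export
diagnose <- function(measurements, thresholds = default_thresholds(),
                     case_id = NA_character_) {
  if (is.data.frame(measurements)) {
    measurements <- unlist(measurements[1, setdiff(names(measurements), "case_id")])
  }
  need <- required_rule_measurements()
  vals <- measurements[need]
  bad <- need[is.na(vals) | !is.finite(vals)]
  if (length(bad)) {
    stop_ceph("required measurements not computable: ",
              paste(bad, collapse = ", "), class = "diagnosis_error")
  }
  anb <- vals[["ANB"]]
  mpsn <- vals[["MP/SN"]]
  oj <- vals[["overjet"]]
  ob <- vals[["overbite"]]
  u1sn <- vals[["U1/SN"]]
  ls <- vals[["UL-EP"]]
  li <- vals[["LL-EP"]]
  th <- thresholds

  sk <- classify_skeletal(anb, th)
  an <- classify_angle(mpsn, th)

  prot1 <- (ls > th$lip_straight_mm & li > th$lip_straight_mm) |
    (ls + li > th$lip_straight_sum_mm)
  prot2 <- (ls > th$lip_classII_mm & li > th$lip_classII_mm) |
    (ls + li >= th$lip_classII_sum_mm)
  doj <- oj >= th$deep_overjet_mm
  openb <- ob < th$openbite_overbite_mm
  ling <- u1sn < th$linguoclination_u1sn_deg
  mild3 <- oj > th$class3_mild_low & oj < 0
  mild3_low <- oj > th$class3_mild_low_lowangle & oj < 0
  sev3 <- oj < th$class3_mild_low
  sev3_low <- oj < th$class3_mild_low_lowangle

  crit <- c(
    CMT_1  = sk == "I"   & an == "average" & !prot1,
    CMT_2  = sk == "I"   & an == "high"    & !prot1,
    CMT_3  = sk == "I"   & an == "low"     & !prot1,
    CMT_4  = sk == "I"   & an %in% c("average", "low") & prot1,
    CMT_5  = sk == "I"   & an == "high"    & prot1,
    CMT_6  = sk == "I"   & doj,
    CMT_7  = sk == "II"  & an %in% c("average", "low") & !prot2,
    CMT_8  = sk == "II"  & an == "high"    & !prot2,
    CMT_9  = sk == "II"  & an == "average" & doj,
    CMT_10 = sk == "II"  & an == "high"    & doj,
    CMT_11 = sk == "II"  & an == "low"     & doj,
    CMT_12 = sk == "II"  & an %in% c("average", "low") & prot2 & oj < th$deep_overjet_mm,
    CMT_13 = sk == "II"  & an == "high"    & prot2 & oj < th$deep_overjet_mm,
    CMT_14 = sk == "II"  & an %in% c("average", "low") & ling,
    CMT_15 = sk == "II"  & an == "high"    & openb,
    CMT_16 = sk == "III" & ((an == "average" & mild3) | (an == "low" & mild3_low)),
    CMT_17 = sk == "III" & an == "high"    & mild3,
    CMT_18 = sk == "III" & an == "average" & sev3,
    CMT_19 = sk == "III" & an == "high"    & sev3,
    CMT_20 = sk == "III" & an == "low"     & sev3_low,
    CMT_21 = sk == "III" & an == "high"    & openb
  )
  matched <- which(crit)
  prec <- cmt_precedence()
  primary <- if (length(matched)) {
    prec[prec %in% matched][1]
  } else "unclassed"
  structure(
    list(case_id = case_id, skeletal_class = unname(sk), angle_type = unname(an),
         matched = unname(matched), primary_cmt = primary,
         trace = crit, thresholds = th),
    class = "ceph_diagnosis")
}

#' @export
print.ceph_diagnosis <- function(x, ...) {
  cat(sprintf("<ceph_diagnosis> %s: skeletal %s, %s angle -> CMT %s (matched: %s)\n",
              x$case_id, x$skeletal_class, x$angle_type,
              as.character(x$primary_cmt),
              if (length(x$matched)) paste(x$matched, collapse = ",") else "none"))
  invisible(x)
}

#' Diagnose every row of a cohort measurement table
#'
#' @param measurements data.frame from [evaluate_cohort()] (with `case_id`).
#' @param thresholds see [default_thresholds()].
#' @return data.frame with case_id, skeletal class, angle type, primary CMT,
#'   matched ids (comma-separated) plus one logical trace column per CMT.
#' @export
diagnose_cohort <- function(measurements, thresholds = default_thresholds()) {
  rows <- lapply(seq_len(nrow(measurements)), function(i) {
    d <- diagnose(measurements[i, ], thresholds,
                  case_id = measurements$case_id[i])
    cbind(data.frame(case_id = d$case_id, skeletal = d$skeletal_class,
                     angle = d$angle_type,
                     primary = as.character(d$primary_cmt),
                     matched = paste(d$matched, collapse = ","),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(d$trace)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

cmt_feature_names <- function() {
  c("1" = "straight profile", "2" = "straight profile", "3" = "straight profile",
    "4" = "bimaxillary protrusion", "5" = "bimaxillary protrusion",
    "6" = "deep overjet",
    "7" = "retruded mandible", "8" = "retruded mandible",
    "9" = "deep overjet", "10" = "deep overjet", "11" = "deep overjet",
    "12" = "bimaxillary protrusion", "13" = "bimaxillary protrusion",
    "14" = "lingually inclined incisors", "15" = "openbite",
    "16" = "protruded mandible", "17" = "protruded mandible",
    "18" = "retruded maxilla and protruded mandible",
    "19" = "retruded maxilla and protruded mandible",
    "20" = "retruded maxilla and protruded mandible",
    "21" = "openbite")
}

#' Clinical labels for templates
#'
#' Applies the rule engine to each template's mean geometry and emits the
#' composite clinical label "skeletal <class>, <angle> angle, <feature>"
#' (e.g. "skeletal I, mean angle, straight profile"); templates matching no
#' criterion are labelled "unclassed".
#'
#' @param templates list of `ceph_template` from [make_templates()].
#' @param thresholds see [default_thresholds()].
#' @return named character vector, one label per template (names = cmt ids of
#'   the cluster model).
#' @export
label_templates <- function(templates, thresholds = default_thresholds()) {
  out <- vapply(templates, function(tp) {
    d <- diagnose(tp$mean_measurements, thresholds,
                  case_id = paste0("CMT_", tp$cmt_id))
    if (identical(d$primary_cmt, "unclassed")) return("unclassed")
    angle_word <- c(low = "low", average = "mean", high = "high")[d$angle_type]
    sprintf("skeletal %s, %s angle, %s", d$skeletal_class, angle_word,
            cmt_feature_names()[[as.character(d$primary_cmt)]])
  }, "")
  names(out) <- vapply(templates, function(tp) as.character(tp$cmt_id), "")
  out
}
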