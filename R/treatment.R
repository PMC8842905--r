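# Pre/post treatment comparison within a template group, and contrasts
# between treatment arms.

# Paired / two-sample t statistics computed directly so that degenerate
# zero-variance data follow the documented convention (all differences 0 ->
# t = 0, p = 1) instead of erroring.
paired_t <- function(d) {
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  if (n < 2L) return(c(t = NA_real_, p = NA_real_))
  if (!is.finite(s) || s < 1e-12) {
    if (abs(m) < 1e-12) return(c(t = 0, p = 1))
    return(c(t = sign(m) * Inf, p = 0))
  }
  tt <- m / (s / sqrt(n))
  c(t = tt, p = 2 * stats::pt(-abs(tt), df = n - 1))
}

student_t2 <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) return(c(t = NA_real_, p = NA_real_))
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  dm <- mean(a) - mean(b)
  if (!is.finite(se) || se < 1e-12) {
    if (abs(dm) < 1e-12) return(c(t = 0, p = 1))
    return(c(t = sign(dm) * Inf, p = 0))
  }
  tt <- dm / se
  c(t = tt, p = 2 * stats::pt(-abs(tt), df = na + nb - 2))
}

#' Compare pre- and post-treatment cohorts
#'
#' Pairs cases by `case_id`, builds the mean pre and post templates, the
#' per-landmark displacement field (post mean minus pre mean, mm), and runs a
#' paired two-sided Student t-test per measurement on the within-patient
#' differences.
#'
#' @param pre,post registered `ceph_cohort`s of the same patients before and
#'   after treatment (every post case needs a pre partner with the same id).
#' @param catalog measurement catalog.
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @param adjust p-value adjustment method (`"none"` by default, matching
#'   descriptive practice; `"holm"` available) — recorded in the result.
#' @param cmt_id optional template id carried into the report.
#' @param arm optional treatment-arm label carried into the report.
#' @return a `ceph_treatment_comparison`: `n_pairs`, `pre_template` /
#'   `post_template` (mean coordinate matrices), `displacement` (p x 2),
#'   and `measurement_stats` (data.frame: pre/post mean and SD, mean
#'   difference, paired t, p, significance flag).
#' @export
compare_treatment <- function(pre, post, catalog = default_catalog(),
                              alpha = 0.05, adjust = c("none", "holm"),
                              cmt_id = NA, arm = NA_character_) {
  adjust <- match.arg(adjust)
  if (!isTRUE(pre$registered) || !isTRUE(post$registered)) {
    stop_ceph("cohorts must be registered", class = "contract_error")
  }
  unpaired <- setdiff(post$meta$case_id, pre$meta$case_id)
  if (length(unpaired)) {
    stop_ceph("post cases without a pre partner: ",
              paste(unpaired, collapse = ", "), class = "pairing_error")
  }
  ids <- post$meta$case_id
  if (length(ids) < 2L) {
    stop_ceph("need at least 2 pre/post pairs", class = "insufficient_pairs")
  }
  pre <- subset_cases(pre, ids)

  pre_mean <- apply(pre$coords, c(1, 2), mean)
  post_mean <- apply(post$coords, c(1, 2), mean)
  displacement <- post_mean - pre_mean

  mpre <- evaluate_cohort(pre, catalog)
  mpost <- evaluate_cohort(post, catalog)
  meas <- setdiff(names(mpre), "case_id")
  stats_rows <- lapply(meas, function(nm) {
    a <- mpre[[nm]]
    b <- mpost[[nm]]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2L) return(NULL)
    d <- b[ok] - a[ok]
    tp <- paired_t(d)
    data.frame(measurement = nm, n = sum(ok),
               pre_mean = mean(a[ok]), pre_sd = stats::sd(a[ok]),
               post_mean = mean(b[ok]), post_sd = stats::sd(b[ok]),
               mean_diff = mean(d), t = tp[["t"]], p = tp[["p"]],
               stringsAsFactors = FALSE)
  })
  ms <- do.call(rbind, stats_rows)
  rownames(ms) <- NULL
  ms$p_adj <- stats::p.adjust(ms$p, method = adjust)
  ms$significant <- ms$p_adj < alpha
  structure(
    list(cmt_id = cmt_id, arm = arm, n_pairs = length(ids),
         pre_template = pre_mean, post_template = post_mean,
         displacement = displacement, measurement_stats = ms,
         alpha = alpha, adjust = adjust,
         diffs = {
           dm <- vapply(ms$measurement, function(nm) {
             a <- mpre[[nm]]; b <- mpost[[nm]]
             ifelse(!is.na(a) & !is.na(b), b - a, NA_real_)
           }, numeric(nrow(mpre)))
           if (is.null(dim(dm))) dm <- matrix(dm, nrow = 1,
                                              dimnames = list(NULL, ms$measurement))
           dm
         }),
    class = "ceph_treatment_comparison")
}

#' @export
print.ceph_treatment_comparison <- function(x, ...) {
  cat(sprintf("<ceph_treatment_comparison> %s%s: %d pairs, %d/%d measurements significant at alpha = %g%s\n",
              if (is.na(x$cmt_id)) "" else paste0("CMT ", x$cmt_id, " "),
              if (is.na(x$arm)) "" else paste0("[", x$arm, "]"),
              x$n_pairs, sum(x$measurement_stats$significant, na.rm = TRUE),
              nrow(x$measurement_stats), x$alpha,
              if (x$adjust != "none") paste0(" (", x$adjust, "-adjusted)") else ""))
  invisible(x)
}

#' Contrast two treatment arms of the same template group
#'
#' Per measurement, the difference of mean pre-to-post changes between arms
#' with a two-sample Student t-test on the per-patient differences; also
#' returns the four templates for overlay rendering.
#'
#' @param a,b `ceph_treatment_comparison` objects for the two arms (same
#'   template group, same measurement set).
#' @param alpha significance level.
#' @return a `ceph_arm_contrast`: per-measurement contrast table and the four
#'   mean templates.
#' @export
contrast_arms <- function(a, b, alpha = 0.05) {
  if (!identical(a$cmt_id, b$cmt_id)) {
    stop_ceph("arm comparisons refer to different templates", class = "contract_error")
  }
  if (!identical(a$measurement_stats$measurement, b$measurement_stats$measurement)) {
    stop_ceph("mismatched measurement sets between arms", class = "contract_error")
  }
  rows <- lapply(a$measurement_stats$measurement, function(nm) {
    da <- a$diffs[, nm]
    db <- b$diffs[, nm]
    da <- da[!is.na(da)]
    db <- db[!is.na(db)]
    tp <- student_t2(da, db)
    data.frame(measurement = nm,
               mean_diff_a = mean(da), mean_diff_b = mean(db),
               contrast = mean(da) - mean(db),
               t = tp[["t"]], p = tp[["p"]],
               significant = is.finite(tp[["p"]]) && tp[["p"]] < alpha,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(
    list(cmt_id = a$cmt_id, arms = c(a$arm, b$arm), contrast_stats = tab,
         templates = list(pre_a = a$pre_template, post_a = a$post_template,
                          pre_b = b$pre_template, post_b = b$post_template),
         alpha = alpha),
    class = "ceph_arm_contrast")
}

#' @export
print.ceph_arm_contrast <- function(x, ...) {
  cat(sprintf("<ceph_arm_contrast> CMT %s: %s vs %s, %d/%d contrasts significant at alpha = %g\n",
              as.character(x$cmt_id), x$arms[1], x$arms[2],
              sum(x$contrast_stats$significant, na.rm = TRUE),
              nrow(x$contrast_stats), x$alpha))
  invisible(x)
}
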