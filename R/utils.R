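#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves going up (the convention used for
#' printed cohort percentages), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ceph <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "cephmorph_error")))
}

check_finite_xy <- function(xy, what = "point") {
  if (!is.numeric(xy) || anyNA(xy) || !all(is.finite(xy))) {
    stop_ceph("non-finite coordinates in ", what, class = "malformed_input")
  }
  invisible(xy)
}
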