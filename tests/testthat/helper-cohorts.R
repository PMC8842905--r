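# Shared fixtures, built in code.

# A random schema-complete landmark configuration: the base wireframe plus
# iid Gaussian jitter, under an arbitrary rigid motion (y-down frame).
random_config <- function(jitter = 2, angle = stats::runif(1, -180, 180),
                          dx = stats::runif(1, -50, 50),
                          dy = stats::runif(1, -50, 50)) {
  m <- base_wireframe() + matrix(stats::rnorm(120, 0, jitter), 60, 2)
  out <- cephmorph:::rigid_transform(m, angle, dx, dy)
  dimnames(out) <- dimnames(m)
  out
}

# Wrap a p x 2 x n coordinate array (mm, image frame) into a cohort.
cohort_from_array <- function(arr, register = TRUE, sex = "female", age = 14) {
  n <- dim(arr)[3]
  meta <- data.frame(case_id = sprintf("c%03d", seq_len(n)),
                     sex = rep_len(sex, n), age = rep_len(age, n),
                     angle_class = "unknown", treatment = "none",
                     timepoint = "pre", scale_factor = 1,
                     stringsAsFactors = FALSE)
  co <- ceph_cohort(arr, meta)
  if (register) co <- register_cohort(co)
  co
}

cohort_from_matrices <- function(mats, ...) {
  arr <- array(unlist(mats), c(60, 2, length(mats)))
  dimnames(arr) <- list(rownames(mats[[1]]), c("x", "y"), NULL)
  cohort_from_array(arr, ...)
}

# Independent angle oracle (atan2-based, unlike the acos implementation).
oracle_angle_at <- function(a, b, c) {
  u <- a - b
  v <- c - b
  abs(atan2(u[1] * v[2] - u[2] * v[1], sum(u * v))) * 180 / pi
}

# Measurement vector builder for rule-engine tests.
rule_measurements <- function(ANB, MPSN, overjet = 3, overbite = 2,
                              U1SN = 105, Ls = 0.5, Li = 0.3) {
  c("ANB" = ANB, "MP/SN" = MPSN, "overjet" = overjet, "overbite" = overbite,
    "U1/SN" = U1SN, "UL-EP" = Ls, "LL-EP" = Li)
}
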