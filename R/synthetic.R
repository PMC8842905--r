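# Fully synthetic landmark cohorts: K morphology prototypes obtained by
# deforming a plausible base wireframe along clinically meaningful axes,
# within-cluster anatomical variation, triple-digitization noise, metadata,
# and optional treatment effects — with stored ground truth.

#' The synthetic base wireframe
#'
#' A hand-constructed, schema-complete 60-landmark configuration in mm with
#' S = (0, 0) and N = (70, 0) (adult-scale anterior cranial base), y-down
#' (+y inferior). It is internally consistent — its measurements land in
#' clinically unremarkable ranges (skeletal I, average angle, straight
#' profile) — but it is a synthetic construction, not a population norm.
#'
#' @return `60 x 2` matrix with landmark codes as rownames.
#' @export
base_wireframe <- function() {
  m <- matrix(c(
    0, 0,      # S
    70, 0,     # N
    -18, 14,   # P
    -12, 30,   # Ba
    52, 20,    # Or
    20, 42,    # PNS
    68, 45,    # ANS
    66, 52,    # A
    64, 60,    # SPr
    60, 60,    # Spr(p)
    64, 76,    # UIE
    60, 52,    # UIA
    61, 58,    # UIR
    40, 68,    # UMC
    40, 55,    # UMR
    22, 32,    # Ptm
    38, 48,    # UMA
    60, 74,    # LIE
    62, 80,    # Id
    58, 80,    # Id(l)
    57, 92,    # LIA
    58, 86,    # LIR
    60, 90,    # B
    61, 102,   # Pg
    58, 108,   # Gn
    54, 110,   # Me
    8, 88,     # Tgo
    2, 80,     # Go
    -2, 74,    # Gop
    -8, 35,    # Ar
    -8, 28,    # Co
    38, 72,    # LMC
    36, 85,    # LMR
    39, 70,    # Interdental-M
    50.5, 72.5, # Interdental-B
    62, 75,    # Interdental-I
    -12, 30,   # Cop
    35, 88,    # LMA
    72, 4,     # Ns
    90, 38,    # Prn
    86, 44,    # Cm
    82, 48,    # Sn
    80, 55,    # As
    82, 62,    # UL
    78, 68,    # Stoms
    77, 72,    # Stomi
    79, 78,    # LL
    74, 90,    # Bs
    74, 102,   # Pos
    70, 108,   # Gns
    64, 112,   # Mes
    40, 118,   # C
    63, 57,    # URP-p
    62, 56,    # URP
    64, 55,    # URA
    65, 56,    # URA-a
    56, 85,    # LRP-p
    56.5, 84,  # LRP
    58.5, 83,  # LRA
    59, 84     # LRA-a
  ), ncol = 2, byrow = TRUE)
  dimnames(m) <- list(ceph_schema()$code, c("x", "y"))
  m
}

# Landmark groups moved together by the deformation axes.
.def_sets <- function() {
  list(
    maxilla = c("ANS", "A", "SPr", "Spr(p)", "As", "Sn", "Cm"),
    mandible_translate = c("Id", "Id(l)", "LIE", "LIA", "LIR", "B", "Pg",
                           "Gn", "Me", "LMC", "LMR", "LMA",
                           "LRP-p", "LRP", "LRA", "LRA-a",
                           "LL", "Stomi", "Bs", "Pos", "Gns", "Mes"),
    chin_rotate = c("Tgo", "Me", "Gn", "Pg", "B", "Bs", "Pos", "Gns", "Mes"),
    upper_incisor = c("UIE", "UIR", "URP-p", "URP", "URA", "URA-a"),
    lower_incisor = c("LIE", "LIR", "LRP-p", "LRP", "LRA", "LRA-a"),
    upper_lip = c("UL", "Stoms"),
    lower_lip = "LL"
  )
}

.rotate_about <- function(m, codes, center, theta_deg) {
  th <- theta_deg * pi / 180
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th))) # y-down: + opens MP
  m[codes, ] <- sweep(sweep(m[codes, , drop = FALSE], 2, center) %*% t(R),
                      2, center, `+`)
  m
}

#' Apply a morphology deformation to a wireframe
#'
#' Deformations are local rigid moves of landmark subsets so that generated
#' prototypes differ along exactly the axes the rule engine reads: sagittal
#' maxilla/mandible shifts (ANB), mandibular-plane rotation about gonion
#' (MP/SN; the dentition stays, emulating dental compensation), incisor
#' block translations and tilts about the apices (overjet, overbite,
#' inclination), and lip offsets (E-line distances). The three interdental
#' midpoints are recomputed afterwards.
#'
#' @param base `60 x 2` wireframe matrix.
#' @param def named list/vector of deformation parameters (all default 0):
#'   `maxilla_dx`, `mandible_dx` (mm), `mp_rotation_deg` (degrees, + opens),
#'   `u1_dx`, `u1_dy`, `l1_dx` (mm), `u1_tilt_deg`, `l1_tilt_deg` (degrees,
#'   + retroclines), `upper_lip_dx`, `lower_lip_dx` (mm).
#' @return deformed `60 x 2` matrix.
#' @export
apply_deformation <- function(base, def = list()) {
  d <- function(nm) def[[nm]] %||% 0
  s <- .def_sets()
  m <- base
  m[s$maxilla, 1] <- m[s$maxilla, 1] + d("maxilla_dx")
  m[s$mandible_translate, 1] <- m[s$mandible_translate, 1] + d("mandible_dx")
  if (d("mp_rotation_deg") != 0) {
    m <- .rotate_about(m, s$chin_rotate, m["Go", ], d("mp_rotation_deg"))
  }
  m[c(s$upper_incisor, "UIA"), 1] <- m[c(s$upper_incisor, "UIA"), 1] + d("u1_dx")
  m[c(s$upper_incisor, "UIA"), 2] <- m[c(s$upper_incisor, "UIA"), 2] + d("u1_dy")
  m[c(s$lower_incisor, "LIA"), 1] <- m[c(s$lower_incisor, "LIA"), 1] + d("l1_dx")
  if (d("u1_tilt_deg") != 0) m <- .rotate_about(m, s$upper_incisor, m["UIA", ], d("u1_tilt_deg"))
  if (d("l1_tilt_deg") != 0) m <- .rotate_about(m, s$lower_incisor, m["LIA", ], d("l1_tilt_deg"))
  m[s$upper_lip, 1] <- m[s$upper_lip, 1] + d("upper_lip_dx")
  m[s$lower_lip, 1] <- m[s$lower_lip, 1] + d("lower_lip_dx")
  m["Interdental-M", ] <- (m["UMC", ] + m["LMC", ]) / 2
  m["Interdental-I", ] <- (m["UIE", ] + m["LIE", ]) / 2
  m["Interdental-B", ] <- (m["Interdental-M", ] + m["Interdental-I", ]) / 2
  m
}

#' Deformation designs for the 21 template archetypes
#'
#' One deformation parameter set per CMT, constructed so that the noiseless
#' prototype geometry satisfies its own Table-of-criteria row: skeletal class
#' via maxilla/mandible shifts, vertical type via mandibular-plane rotation,
#' and the special feature via incisor/lip moves. Class II prototypes without
#' deep overjet carry an upper-incisor retraction (dental compensation).
#'
#' @param scale multiplier applied to every deformation magnitude (1 =
#'   the designed, clinically plausible magnitudes).
#' @return named list of 21 deformation parameter lists (`CMT_1` ...
#'   `CMT_21`).
#' @export
cmt_prototype_designs <- function(scale = 1) {
  D <- function(...) {
    v <- list(...)
    lapply(v, function(x) x * scale)
  }
  list(
    CMT_1  = D(),
    CMT_2  = D(mp_rotation_deg = 9),
    CMT_3  = D(mp_rotation_deg = -6),
    CMT_4  = D(u1_dx = 2, l1_dx = 2, upper_lip_dx = 4, lower_lip_dx = 4),
    CMT_5  = D(mp_rotation_deg = 9, u1_dx = 2, l1_dx = 2, upper_lip_dx = 4, lower_lip_dx = 4),
    CMT_6  = D(u1_dx = 5),
    CMT_7  = D(mandible_dx = -6, u1_dx = -6),
    CMT_8  = D(mandible_dx = -6, mp_rotation_deg = 9, u1_dx = -6),
    CMT_9  = D(mandible_dx = -6),
    CMT_10 = D(mandible_dx = -6, mp_rotation_deg = 9),
    CMT_11 = D(mandible_dx = -6, mp_rotation_deg = -8),
    CMT_12 = D(mandible_dx = -6, u1_dx = -6, upper_lip_dx = 5, lower_lip_dx = 10),
    CMT_13 = D(mandible_dx = -6, mp_rotation_deg = 9, u1_dx = -6, upper_lip_dx = 5, lower_lip_dx = 10),
    CMT_14 = D(mandible_dx = -6, u1_dx = 2, u1_tilt_deg = 25),
    CMT_15 = D(mandible_dx = -6, mp_rotation_deg = 9, u1_dx = -6, u1_dy = -4),
    CMT_16 = D(mandible_dx = 5, mp_rotation_deg = 2),
    CMT_17 = D(mandible_dx = 7, mp_rotation_deg = 12),
    CMT_18 = D(maxilla_dx = -3, mandible_dx = 8, mp_rotation_deg = 4),
    CMT_19 = D(maxilla_dx = -3, mandible_dx = 8, mp_rotation_deg = 13),
    CMT_20 = D(maxilla_dx = -3, mandible_dx = 8, mp_rotation_deg = -4),
    CMT_21 = D(mandible_dx = 7, mp_rotation_deg = 12, u1_dy = -4)
  )
}

#' Build prototype configurations from deformation designs
#'
#' @param designs list of deformation parameter lists (default: the 21
#'   template archetypes).
#' @param base base wireframe.
#' @return array `60 x 2 x K` of prototype coordinates (mm).
#' @export
make_prototypes <- function(designs = cmt_prototype_designs(),
                            base = base_wireframe()) {
  K <- length(designs)
  arr <- array(NA_real_, c(nrow(base), 2, K),
               dimnames = list(rownames(base), c("x", "y"),
                               names(designs) %||% paste0("proto_", seq_len(K))))
  for (k in seq_len(K)) arr[, , k] <- apply_deformation(base, designs[[k]])
  arr
}

#' Synthetic cohort configuration
#'
#' Defaults mirror the emulated study conditions: digitization in triples
#' with sigma_dig = 0.3 mm replicate noise, within-cluster anatomical SD
#' 1.5 mm per coordinate, female share 66.3%, age ~ truncated normal
#' (mean 14.35, SD 4.99, range 7-62 years), magnification scale factor 1.1.
#'
#' @param seed integer seed; fully determines the generated cohort.
#' @param designs prototype deformation designs (default the 21 archetypes).
#' @param n_per_cluster integer vector (recycled over prototypes).
#' @param sigma_within per-coordinate within-cluster SD in mm.
#' @param sigma_dig digitization replicate SD in mm.
#' @param replicate_count digitization replicates per landmark (1-3).
#' @param scale_factor image-units-per-mm magnification written into the
#'   generated files (the generator multiplies mm by this factor).
#' @param p_female probability of sex = female.
#' @param age_mean,age_sd,age_range truncated-normal age model (years).
#' @param treatment_effect optional `60 x 2` displacement matrix (mm) added
#'   to each patient's true geometry for a "post" copy, or a list of such
#'   matrices named by treatment arm (arms assigned round-robin).
#' @return a `ceph_sim_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             designs = cmt_prototype_designs(),
                             n_per_cluster = 40L,
                             sigma_within = 1.5,
                             sigma_dig = 0.3,
                             replicate_count = 3L,
                             scale_factor = 1.1,
                             p_female = 0.663,
                             age_mean = 14.35, age_sd = 4.99,
                             age_range = c(7, 62),
                             treatment_effect = NULL) {
  stopifnot(sigma_within >= 0, sigma_dig >= 0,
            replicate_count %in% 1:3, scale_factor > 0)
  n_per_cluster <- rep_len(as.integer(n_per_cluster), length(designs))
  if (any(n_per_cluster < 1L)) {
    stop_ceph("n_per_cluster entries must be >= 1", class = "configuration_error")
  }
  structure(list(seed = as.integer(seed), designs = designs,
                 n_per_cluster = n_per_cluster,
                 sigma_within = sigma_within, sigma_dig = sigma_dig,
                 replicate_count = as.integer(replicate_count),
                 scale_factor = scale_factor, p_female = p_female,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 treatment_effect = treatment_effect),
            class = "ceph_sim_config")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic landmark cohort
#'
#' Each case is its prototype plus isotropic within-cluster Gaussian
#' perturbation; each landmark is emitted as `replicate_count` digitization
#' points (true point + digitization noise), in image units
#' (mm x `scale_factor`). Output is deterministic under the seed.
#'
#' @param config a `ceph_sim_config`.
#' @return a `ceph_sim` list: `landmarks` (replicate data.frame in the
#'   ingest dialect, image units), `meta` (metadata data.frame; includes the
#'   "post" copies when a treatment effect is configured), and `truth`
#'   (per-case true cluster and arm, the prototype array, the per-arm
#'   displacement fields, and the config).
#' @export
generate_cohort <- function(config) {
  set.seed(config$seed)
  protos <- make_prototypes(config$designs)
  K <- dim(protos)[3]
  p <- dim(protos)[1]
  nk <- config$n_per_cluster
  N <- sum(nk)
  cluster <- rep(seq_len(K), nk)
  ids <- sprintf("case_%04d", seq_len(N))

  true_pre <- protos[, , cluster, drop = FALSE] +
    array(stats::rnorm(p * 2 * N, 0, config$sigma_within), c(p, 2, N))

  sex <- ifelse(stats::runif(N) < config$p_female, "female", "male")
  age <- round_half_up(rtruncnorm1(N, config$age_mean, config$age_sd,
                                   config$age_range[1], config$age_range[2]), 1)

  eff <- config$treatment_effect
  arms <- NA_character_
  has_post <- !is.null(eff)
  if (has_post && !is.list(eff)) eff <- list(treated = eff)
  if (has_post) {
    arms <- rep_len(names(eff), N)
  }

  emit <- function(true_coords) {
    n <- dim(true_coords)[3]
    reps <- aperm(array(true_coords, c(p, 2, n, config$replicate_count)), c(1, 2, 4, 3))
    reps <- reps + array(stats::rnorm(length(reps), 0, config$sigma_dig), dim(reps))
    reps <- reps * config$scale_factor
    codes <- dimnames(protos)[[1]]
    data.frame(
      case_id = rep(ids, each = p * config$replicate_count),
      landmark = rep(rep(codes, each = config$replicate_count), times = n),
      replicate = rep(seq_len(config$replicate_count), times = p * n),
      x = as.vector(aperm(reps[, 1, , , drop = FALSE], c(3, 1, 2, 4))),
      y = as.vector(aperm(reps[, 2, , , drop = FALSE], c(3, 1, 2, 4))),
      stringsAsFactors = FALSE)
  }

  lm_pre <- emit(true_pre)
  meta_pre <- data.frame(case_id = ids, sex = sex, age = age,
                         angle_class = "unknown",
                         treatment = if (has_post) arms else "none",
                         timepoint = "pre",
                         scale_factor = config$scale_factor,
                         stringsAsFactors = FALSE)
  landmarks <- lm_pre
  meta <- meta_pre
  if (has_post) {
    true_post <- true_pre
    for (a in names(eff)) {
      sel <- which(arms == a)
      true_post[, , sel] <- true_post[, , sel] +
        array(rep(as.vector(eff[[a]]), length(sel)), c(p, 2, length(sel)))
    }
    lm_post <- emit(true_post)
    meta_post <- meta_pre
    meta_post$timepoint <- "post"
    # post rows keep the same case ids; the timepoint column separates them
    landmarks <- rbind(lm_pre, lm_post)
    landmarks$timepoint <- rep(c("pre", "post"), c(nrow(lm_pre), nrow(lm_post)))
    meta <- rbind(meta_pre, meta_post)
  }

  structure(
    list(landmarks = landmarks, meta = meta,
         truth = list(cases = data.frame(case_id = ids, cluster = cluster,
                                         arm = if (has_post) arms else NA_character_,
                                         stringsAsFactors = FALSE),
                      prototypes = protos,
                      treatment_effect = eff,
                      config = config)),
    class = "ceph_sim")
}

#' Ingest a generated cohort
#'
#' Runs the generated replicate table through the standard ingest pipeline
#' (calibration, magnification correction, registration).
#'
#' @param sim a `ceph_sim` from [generate_cohort()].
#' @param timepoint `"pre"` or `"post"`.
#' @return a registered `ceph_cohort`.
#' @export
ingest_simulated <- function(sim, timepoint = "pre") {
  lm <- sim$landmarks
  meta <- sim$meta
  if ("timepoint" %in% names(lm)) {
    lm <- lm[lm$timepoint == timepoint, setdiff(names(lm), "timepoint")]
  } else if (timepoint != "pre") {
    stop_ceph("simulation has no post timepoint", class = "configuration_error")
  }
  meta <- meta[meta$timepoint == timepoint, ]
  ingest_cohort(lm, meta)
}

#' Monte-Carlo flag rate of the triple-digitization rule
#'
#' Estimates, for three i.i.d. isotropic Gaussian replicates with SD
#' `sigma_dig`, the probability that the 2x max/min pairwise-distance rule
#' fires. The statistic is scale-free: the rate does not depend on
#' `sigma_dig` (except at exactly 0, where coincident replicates never
#' flag).
#'
#' @param sigma_dig replicate SD (mm or image units).
#' @param n number of Monte-Carlo triples (>= 1e5 for the stated precision).
#' @param seed integer seed.
#' @return estimated flag probability, with attribute `se` (binomial
#'   standard error).
#' @export
expected_flag_rate <- function(sigma_dig, n = 1e5, seed = 1L) {
  if (sigma_dig < 0) stop_ceph("sigma_dig must be >= 0", class = "configuration_error")
  if (sigma_dig == 0) {
    out <- 0
    attr(out, "se") <- 0
    return(out)
  }
  set.seed(seed)
  x <- matrix(stats::rnorm(3 * n, 0, sigma_dig), ncol = 3)
  y <- matrix(stats::rnorm(3 * n, 0, sigma_dig), ncol = 3)
  d12 <- sqrt((x[, 1] - x[, 2])^2 + (y[, 1] - y[, 2])^2)
  d13 <- sqrt((x[, 1] - x[, 3])^2 + (y[, 1] - y[, 3])^2)
  d23 <- sqrt((x[, 2] - x[, 3])^2 + (y[, 2] - y[, 3])^2)
  mx <- pmax(d12, d13, d23)
  mn <- pmin(d12, d13, d23)
  flag <- ifelse(mx < 1e-9, FALSE, ifelse(mn < 1e-9, TRUE, mx > 2 * mn))
  out <- mean(flag)
  attr(out, "se") <- sqrt(out * (1 - out) / n)
  out
}

#' Prototype subsets for cluster-recovery experiments
#'
#' For each K in 2..8, a subset of the 21 template archetypes whose pairwise
#' coordinate-vector separations are as uniform as possible (max/min
#' separation ratio minimized, minimum separation at least 15 mm at
#' deformation scale 1). Near-uniform separations avoid nested super-group
#' structure, so the mean-silhouette k selection is judged on cluster count,
#' not on hierarchy depth. Recovery experiments combine these subsets with
#' [cmt_prototype_designs()]`(scale = 3)`, giving minimum separations of
#' 88-190 mm against the default 1.5 mm within-cluster SD (separation/noise
#' well above 10).
#'
#' @param K number of prototypes (2-8).
#' @return integer vector of K archetype ids.
#' @export
recovery_prototype_ids <- function(K) {
  stopifnot(K >= 2, K <= 8)
  list(c(4L, 7L),
       c(3L, 15L, 17L),
       c(1L, 5L, 10L, 12L),
       c(2L, 6L, 11L, 12L, 15L),
       c(2L, 3L, 9L, 13L, 16L, 17L),
       c(3L, 5L, 6L, 10L, 11L, 12L, 16L),
       c(5L, 6L, 7L, 10L, 11L, 17L, 18L, 20L))[[K - 1L]]
}
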