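test_that("schema has 60 unique landmarks split 46 hard / 14 soft", {
  sch <- ceph_schema()
  expect_silent(validate_schema(sch))
  expect_identical(nrow(sch), 60L)
  expect_identical(sum(sch$tissue == "hard"), 46L)
  expect_identical(sum(sch$tissue == "soft"), 14L)
  expect_false(anyDuplicated(sch$code) > 0)
})

test_that("triple-digitization calibration averages and flags per the 2x rule", {
  # all replicates identical: mean there, no flag
  r <- calibrate_landmark(rbind(c(0, 0), c(0, 0), c(0, 0)))
  expect_equal(r$point, c(0, 0))
  expect_false(r$flag)
  # distances 1, 2, 3: max 3 > 2 * min 1 -> flag
  r <- calibrate_landmark(rbind(c(0, 0), c(1, 0), c(3, 0)))
  expect_equal(r$point, c(4 / 3, 0))
  expect_true(r$flag)
  # distances 1, 1, 2: max equals 2 * min exactly -> strict rule, no flag
  r <- calibrate_landmark(rbind(c(0, 0), c(1, 0), c(2, 0)))
  expect_equal(r$point, c(1, 0))
  expect_false(r$flag)
  # two coincident replicates plus a distinct one: infinite ratio -> flag
  expect_true(calibrate_landmark(rbind(c(0, 0), c(0, 0), c(1, 0)))$flag)
  # fewer than 3 replicates: mean of what exists, never flagged
  r <- calibrate_landmark(rbind(c(0, 0), c(4, 2)))
  expect_equal(r$point, c(2, 1))
  expect_false(r$flag)
  expect_false(calibrate_landmark(rbind(c(5, 5)))$flag)
  expect_error(calibrate_landmark(rbind(c(NA, 0), c(0, 0), c(0, 0))),
               class = "malformed_input")
})

test_that("calibration mean and flag are replicate-permutation invariant", {
  set.seed(7)
  for (i in 1:50) {
    reps <- matrix(rnorm(6), 3, 2)
    base <- calibrate_landmark(reps)
    for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
      r <- calibrate_landmark(reps[perm, ])
      expect_equal(r$point, base$point)
      expect_identical(r$flag, base$flag)
    }
  }
})

test_that("magnification correction divides by the scale factor", {
  expect_equal(apply_magnification(c(11, 22), 1.1), c(10, 20))
  expect_equal(apply_magnification(c(5, 5), 1), c(5, 5))
  expect_equal(apply_magnification(c(0, 0), 3.7), c(0, 0))
  expect_error(apply_magnification(c(1, 1), 0), class = "configuration_error")
  expect_error(apply_magnification(c(1, 1), -2), class = "configuration_error")
})

test_that("registration maps S to the origin and N onto the positive x-axis", {
  m <- base_wireframe()
  # axis-aligned input: pure translation
  m1 <- m
  m1["S", ] <- c(10, 20); m1["N", ] <- c(30, 20); m1["A", ] <- c(10, 25)
  r <- cephmorph:::register_matrix(m1)
  expect_equal(unname(r["S", ]), c(0, 0))
  expect_equal(unname(r["N", ]), c(20, 0))
  expect_equal(unname(r["A", ]), c(0, 5))
  # quarter-turn frame: rotation with det +1, no reflection
  m2 <- m
  m2["S", ] <- c(0, 0); m2["N", ] <- c(0, 10); m2["A", ] <- c(1, 0)
  r2 <- cephmorph:::register_matrix(m2)
  expect_equal(unname(r2["N", ]), c(10, 0))
  expect_equal(unname(r2["A", ]), c(0, -1))
  expect_error(
    cephmorph:::register_matrix({m3 <- m; m3["N", ] <- m3["S", ] + c(0.05, 0); m3}),
    class = "degenerate_frame")
})

test_that("registration is an exact isometry and idempotent", {
  set.seed(11)
  for (i in 1:25) {
    m <- random_config()
    co <- cohort_from_matrices(list(m))
    r <- case_coords(co, 1)
    expect_lt(max(abs(dist(m) - dist(r))), 1e-9)
    r2 <- cephmorph:::register_matrix(r)
    expect_lt(max(abs(r2 - r)), 1e-9)
  }
})

test_that("ingest pipeline calibrates, corrects magnification and registers", {
  set.seed(3)
  cfg <- synthetic_config(seed = 5, designs = cmt_prototype_designs()[1:2],
                          n_per_cluster = 4, scale_factor = 1.25)
  sim <- generate_cohort(cfg)
  co <- ingest_cohort(sim$landmarks, sim$meta)
  expect_s3_class(co, "ceph_cohort")
  expect_true(co$registered)
  expect_identical(n_cases(co), 8L)
  expect_equal(unname(co$coords["S", , 1]), c(0, 0))
  expect_lt(max(abs(co$coords["N", 2, ])), 1e-9)
  # noiseless generation reproduces the prototypes exactly through the
  # full CSV dialect + calibration + magnification + registration path
  cfg0 <- synthetic_config(seed = 6, designs = cmt_prototype_designs()[1:2],
                           n_per_cluster = 2, sigma_within = 0, sigma_dig = 0,
                           scale_factor = 1.5)
  sim0 <- generate_cohort(cfg0)
  co0 <- ingest_cohort(sim0$landmarks, sim0$meta)
  protos <- sim0$truth$prototypes
  for (i in 1:4) {
    k <- sim0$truth$cases$cluster[i]
    expect_lt(max(abs(case_coords(co0, i) - protos[, , k])), 1e-9)
  }
})

test_that("landmark CSV dialect round-trips losslessly", {
  cfg <- synthetic_config(seed = 9, designs = cmt_prototype_designs()[1:3],
                          n_per_cluster = 3)
  sim <- generate_cohort(cfg)
  tmp <- tempfile(fileext = ".csv")
  write_landmark_csv(sim$landmarks, tmp)
  back <- read_landmark_csv(tmp)
  expect_identical(back$case_id, sim$landmarks$case_id)
  expect_identical(back$landmark, sim$landmarks$landmark)
  expect_lt(max(abs(back$x - sim$landmarks$x)), 1e-9)
  expect_lt(max(abs(back$y - sim$landmarks$y)), 1e-9)
  co_a <- ingest_cohort(sim$landmarks, sim$meta)
  co_b <- ingest_cohort(back, sim$meta)
  expect_lt(max(abs(co_a$coords - co_b$coords)), 1e-9)
})

test_that("TPS reader/writer round-trips the calibrated single-replicate form", {
  cfg <- synthetic_config(seed = 4, designs = cmt_prototype_designs()[1:2],
                          n_per_cluster = 2, replicate_count = 1)
  sim <- generate_cohort(cfg)
  co <- ingest_cohort(sim$landmarks, sim$meta, register = FALSE)
  tmp <- tempfile(fileext = ".tps")
  # write in image units so SCALE round-trips the magnification
  img <- co
  img$coords <- img$coords * cfg$scale_factor
  write_tps(img, tmp)
  tp <- read_tps(tmp)
  expect_identical(unname(tp$scale), rep(cfg$scale_factor, 4))
  meta2 <- co$meta
  co2 <- ingest_cohort(tp$landmarks, meta2, register = FALSE)
  expect_lt(max(abs(co2$coords - co$coords)), 1e-8)
})

test_that("cohort summary reproduces printed-style percentages", {
  meta <- data.frame(
    case_id = as.character(1:2249),
    sex = rep(c("male", "female"), c(758, 1491)),
    age = 14,
    angle_class = rep(c("I", "II", "III"), c(945, 872, 432)),
    treatment = "none", timepoint = "pre", scale_factor = 1,
    stringsAsFactors = FALSE)
  s <- summarize_cohort(meta)
  expect_identical(s$n, 2249L)
  expect_equal(s$sex$percent[s$sex$level == "male"], 33.7)
  expect_equal(s$sex$percent[s$sex$level == "female"], 66.3)
  expect_equal(s$angle_class$percent[1:3], c(42.0, 38.8, 19.2))
  # percentages sum to 100 within rounding slack
  expect_lt(abs(sum(s$sex$percent) - 100), 0.2)
  expect_lt(abs(sum(s$angle_class$percent) - 100), 0.2)
  # degenerate cohort
  s1 <- summarize_cohort(meta[1, ])
  expect_equal(s1$sex$percent[s1$sex$level == "male"], 100.0)
  expect_error(summarize_cohort(meta[0, ]), class = "empty_input")
})
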