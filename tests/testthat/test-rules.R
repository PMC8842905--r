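test_that("skeletal banding: closed Class-I interval, II above, III below", {
  expect_identical(classify_skeletal(2.0), "I")
  expect_identical(classify_skeletal(4.7), "I")  # inclusive upper bound
  expect_identical(classify_skeletal(0.0), "I")  # inclusive lower bound
  expect_identical(classify_skeletal(4.8), "II")
  expect_identical(classify_skeletal(-1.0), "III")
})

test_that("vertical banding: closed average band between 27 and 37 degrees", {
  expect_identical(classify_angle(30), "average")
  expect_identical(classify_angle(27), "average")
  expect_identical(classify_angle(26.9), "low")
  expect_identical(classify_angle(37), "average")
  expect_identical(classify_angle(40), "high")
})

test_that("banding partitions the real line uniquely", {
  set.seed(303)
  anb <- runif(1e4, -15, 15)
  mpsn <- runif(1e4, 10, 55)
  sk <- classify_skeletal(anb)
  an <- classify_angle(mpsn)
  expect_true(all(sk %in% c("I", "II", "III")))
  expect_true(all(an %in% c("low", "average", "high")))
  # boundary self-consistency: each value maps to exactly one band
  expect_identical(classify_skeletal(anb), sk)
  expect_identical(classify_angle(mpsn), an)
})

test_that("tabulated worked diagnoses resolve to the expected templates", {
  # skeletal II, high angle, overjet >= 8 mm
  d <- diagnose(rule_measurements(ANB = 7, MPSN = 40, overjet = 9))
  expect_identical(d$primary_cmt, 10L)
  # skeletal I, average angle, straight lips
  d <- diagnose(rule_measurements(ANB = 2, MPSN = 30, Ls = 0.5, Li = 0.3,
                                  overjet = 3, overbite = 2))
  expect_identical(d$primary_cmt, 1L)
  # skeletal III, average angle, overjet below -3 mm
  d <- diagnose(rule_measurements(ANB = -4, MPSN = 30, overjet = -4))
  expect_identical(d$primary_cmt, 18L)
})

test_that("deep-overjet boundary is inclusive at 8 mm", {
  expect_identical(diagnose(rule_measurements(ANB = 7, MPSN = 30, overjet = 8))$primary_cmt, 9L)
  expect_identical(diagnose(rule_measurements(ANB = 7, MPSN = 30, overjet = 7.9))$primary_cmt, 7L)
})

test_that("class III overjet ranges follow the tabulated strict bounds", {
  # average angle: (-3, 0) mild, < -3 severe, exactly -3 unmatched
  expect_identical(diagnose(rule_measurements(ANB = -3, MPSN = 30, overjet = -1))$primary_cmt, 16L)
  expect_identical(diagnose(rule_measurements(ANB = -3, MPSN = 30, overjet = -3.5))$primary_cmt, 18L)
  expect_identical(diagnose(rule_measurements(ANB = -3, MPSN = 30, overjet = -3))$primary_cmt, "unclassed")
  # low angle: mild narrows to (-2, 0) and severe widens to < -2
  expect_identical(diagnose(rule_measurements(ANB = -3, MPSN = 24, overjet = -1.5))$primary_cmt, 16L)
  expect_identical(diagnose(rule_measurements(ANB = -3, MPSN = 24, overjet = -2.5))$primary_cmt, 20L)
  # high angle mild
  expect_identical(diagnose(rule_measurements(ANB = -3, MPSN = 40, overjet = -1))$primary_cmt, 17L)
  expect_identical(diagnose(rule_measurements(ANB = -3, MPSN = 40, overjet = -5))$primary_cmt, 19L)
})

test_that("linguoclination and class II lip split behave per the criteria", {
  # U1/SN below 90 in class II, average angle -> CMT_14 beats the lip split
  d <- diagnose(rule_measurements(ANB = 6, MPSN = 30, U1SN = 85))
  expect_identical(d$primary_cmt, 14L)
  expect_true(7L %in% d$matched)
  # protruded lips, class II thresholds (both > 2.5 or sum >= 4)
  expect_identical(diagnose(rule_measurements(ANB = 6, MPSN = 30, Ls = 3, Li = 3))$primary_cmt, 12L)
  expect_identical(diagnose(rule_measurements(ANB = 6, MPSN = 42, Ls = 1, Li = 3.5))$primary_cmt, 13L) # sum rule
  expect_identical(diagnose(rule_measurements(ANB = 6, MPSN = 42, Ls = 1, Li = 1))$primary_cmt, 8L)
  # class I protrusion at the 1 mm / 2 mm thresholds
  expect_identical(diagnose(rule_measurements(ANB = 2, MPSN = 30, Ls = 1.5, Li = 1.5))$primary_cmt, 4L)
  expect_identical(diagnose(rule_measurements(ANB = 2, MPSN = 40, Ls = 1.5, Li = 1.5))$primary_cmt, 5L)
})

test_that("open bite takes precedence over deep overjet within its stratum", {
  d <- diagnose(rule_measurements(ANB = 6, MPSN = 42, overjet = 9, overbite = -1))
  expect_identical(d$primary_cmt, 15L)
  expect_true(all(c(10L, 15L) %in% d$matched))
  # class III high angle: open bite beats severe overjet
  d2 <- diagnose(rule_measurements(ANB = -4, MPSN = 42, overjet = -5, overbite = -2))
  expect_identical(d2$primary_cmt, 21L)
  expect_true(19L %in% d2$matched)
})

test_that("diagnosis is deterministic and errors on missing inputs", {
  m <- rule_measurements(ANB = 3, MPSN = 30)
  expect_identical(diagnose(m)$primary_cmt, diagnose(m)$primary_cmt)
  m2 <- m
  m2[["overjet"]] <- NA
  expect_error(diagnose(m2), class = "diagnosis_error")
  expect_error(diagnose(m2), "overjet")
})

test_that("random measurement vectors always get a unique primary or unclassed", {
  set.seed(909)
  for (i in 1:500) {
    m <- rule_measurements(ANB = runif(1, -10, 12), MPSN = runif(1, 15, 50),
                           overjet = runif(1, -8, 12), overbite = runif(1, -4, 6),
                           U1SN = runif(1, 70, 130), Ls = runif(1, -6, 8),
                           Li = runif(1, -6, 8))
    d <- diagnose(m)
    expect_length(d$primary_cmt, 1L)
    if (length(d$matched)) expect_true(d$primary_cmt %in% d$matched)
    expect_length(d$trace, 21L)
  }
})

test_that("each template archetype geometry diagnoses to its own template", {
  protos <- make_prototypes()
  for (k in 1:21) {
    d <- diagnose(measure_case(protos[, , k]))
    expect_identical(d$primary_cmt, k)
  }
})

test_that("template labels follow the composite naming scheme", {
  m2 <- base_wireframe()
  m2["Pg", 1] <- m2["Pg", 1] + 0.5
  co <- cohort_from_matrices(list(base_wireframe(), m2))
  cl <- cluster_cases(build_features(co), k = 1, min_size = 1)
  tp <- make_templates(cl, co)
  expect_identical(unname(label_templates(tp)),
                   "skeletal I, mean angle, straight profile")
  # open-bite archetype label carries the openbite feature
  protos <- make_prototypes()
  tpl <- list(structure(list(cmt_id = 1, n = 1, mean_coords = protos[, , 15],
                             mean_measurements = measure_case(protos[, , 15])),
                        class = "ceph_template"))
  expect_match(label_templates(tpl), "openbite")
  expect_match(label_templates(tpl), "^skeletal II, high angle")
})
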