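test_that("feature matrix drops exactly the frame-fixed coordinates", {
  set.seed(8)
  arr <- array(NA_real_, c(60, 2, 10))
  for (i in 1:10) arr[, , i] <- random_config()
  dimnames(arr) <- list(rownames(base_wireframe()), c("x", "y"), NULL)
  co <- cohort_from_array(arr)
  fm <- build_features(co)
  expect_identical(ncol(fm$X), 117L)
  expect_setequal(fm$dropped, c("S_x", "S_y", "N_y"))
  expect_true(all(apply(fm$X, 2, var) > 1e-12))
  expect_identical(nrow(fm$X), 10L)
})

test_that("identical cases give equal feature rows; single case is rejected", {
  m <- base_wireframe()
  m2 <- m
  m2["Me", ] <- m2["Me", ] + c(1, 2)
  co <- cohort_from_matrices(list(m, m, m, m2))
  fm <- build_features(co)
  expect_lt(max(abs(sweep(fm$X[1:3, ], 2, fm$X[1, ]))), 1e-9)
  co1 <- cohort_from_matrices(list(m))
  expect_error(build_features(co1), class = "contract_error")
})

test_that("cases with missing landmarks are rejected with a named payload", {
  arr <- array(rep(base_wireframe(), 3), c(60, 2, 3))
  dimnames(arr) <- list(rownames(base_wireframe()), c("x", "y"), NULL)
  arr[, , 2] <- arr[, , 2] + 1 # keep registration valid
  co <- cohort_from_array(arr)
  co$coords["Prn", , 2] <- NA
  err <- tryCatch(build_features(co), error = identity)
  expect_s3_class(err, "missing_landmarks")
  expect_identical(err$rejected, "c002")
})

test_that("two well-separated point clouds are recovered exactly at k = auto", {
  set.seed(13)
  n <- 50
  X <- rbind(matrix(rnorm(n * 2, 0, 1), n, 2),
             matrix(rnorm(n * 2, 100, 1), n, 2))
  colnames(X) <- c("u", "v")
  truth <- rep(1:2, each = n)
  for (method in c("ward", "kmeans")) {
    cl <- cluster_cases(X, method = method, k = "auto", k_max = 10, seed = 2)
    expect_identical(cl$k_raw, 2L)
    expect_equal(cluster_agreement(truth, cl$assignments), 1)
    # silhouette at k = 2 beats every k in 3..10
    expect_identical(cl$silhouette$k[which.max(cl$silhouette$mean_silhouette)], 2L)
  }
})

test_that("clusters below min_size are pruned into the unclassed pool", {
  set.seed(17)
  X <- rbind(matrix(rnorm(100, 0, 1), 50, 2),
             matrix(rnorm(100, 60, 1), 50, 2),
             matrix(rnorm(8, 120, 1), 4, 2))
  cl <- cluster_cases(X, k = 3, min_size = 5)
  expect_identical(cl$n_cmt, 2L)
  expect_identical(length(cl$unclassed), 4L)
  expect_identical(sort(unname(cl$cmt_sizes)), c(50L, 50L))
  # partition invariant: CMT members + unclassed = cohort
  expect_identical(sum(cl$cmt_sizes) + length(cl$unclassed), nrow(X))
  # pruning never removes a cluster of size >= min_size
  expect_true(all(table(cl$assignments)[as.character(cl$pruned)] < 5))
})

test_that("all-identical points collapse to a single unpruned cluster", {
  X <- matrix(1, 20, 4)
  cl <- cluster_cases(X, k = "auto")
  expect_identical(cl$k_raw, 1L)
  expect_identical(cl$n_cmt, 1L)
  expect_length(cl$unclassed, 0L)
})

test_that("ward mode is deterministic and kmeans reproducible under a seed", {
  set.seed(19)
  X <- matrix(rnorm(200), 50, 4)
  a <- cluster_cases(X, k = 4)
  b <- cluster_cases(X, k = 4)
  expect_identical(a$assignments, b$assignments)
  k1 <- cluster_cases(X, method = "kmeans", k = 4, seed = 99)
  k2 <- cluster_cases(X, method = "kmeans", k = 4, seed = 99)
  expect_identical(k1$assignments, k2$assignments)
  expect_error(cluster_cases(X, k = 51), class = "parameter_error")
})

test_that("templates are member coordinate means in the registered frame", {
  m <- base_wireframe()
  m2 <- m; m2[c("Pg", "Gn", "Me", "B"), 1] <- m2[c("Pg", "Gn", "Me", "B"), 1] + 4
  co <- cohort_from_matrices(list(m, m, m2, m2))
  # two artificial clusters: {1,2} and {3,4}
  fm <- build_features(co)
  cl <- cluster_cases(fm, k = 2, min_size = 1)
  tps <- make_templates(cl, co)
  expect_length(tps, 2L)
  for (tp in tps) {
    idx <- which(cl$cmt == tp$cmt_id)
    manual <- apply(co$coords[, , idx, drop = FALSE], c(1, 2), mean)
    expect_lt(max(abs(tp$mean_coords - manual)), 1e-9)
    expect_equal(unname(tp$mean_coords["S", ]), c(0, 0))
    expect_lt(abs(tp$mean_coords["N", 2]), 1e-9)
    expect_false(is.na(tp$mean_measurements["SNA"]))
  }
  # a cluster of one repeated case equals that case; midpoint for two members
  one <- tps[[which(vapply(tps, function(t) max(abs(t$mean_coords - case_coords(co, 1))), 0) < 1e-9)]]
  expect_lt(max(abs(one$mean_coords - case_coords(co, 1))), 1e-9)
})

test_that("template recovery: cluster means land within 3 RMS-SE of prototypes", {
  ids <- recovery_prototype_ids(3)
  cfg <- synthetic_config(seed = 23, designs = cmt_prototype_designs(scale = 3)[ids],
                          n_per_cluster = 30)
  sim <- generate_cohort(cfg)
  co <- ingest_simulated(sim)
  cl <- cluster_cases(build_features(co), k = 3, min_size = 5)
  tps <- make_templates(cl, co)
  protos <- sim$truth$prototypes
  for (tp in tps) {
    devs <- vapply(seq_len(dim(protos)[3]), function(k) {
      sqrt(mean((tp$mean_coords - protos[, , k])^2))
    }, 0)
    members <- co$coords[, , which(!is.na(cl$cmt) & cl$cmt == tp$cmt_id), drop = FALSE]
    se_rms <- sqrt(mean(apply(members, c(1, 2), stats::var)) / tp$n)
    expect_lt(min(devs), 3 * se_rms)
  }
})

test_that("cmt_distribution reproduces printed-style shares", {
  # distribution arithmetic at the printed cohort scale
  m <- base_wireframe()
  co <- cohort_from_matrices(rep(list(m, m + 0.5), 5))
  fm <- build_features(co)
  cl <- cluster_cases(fm, k = 2, min_size = 1)
  tab <- cmt_distribution(cl, co)
  expect_identical(tab$cmt[nrow(tab)], "total")
  expect_equal(tab$percent[tab$cmt == "total"], 100.0)
  expect_equal(sum(tab$n[tab$cmt != "total"]), n_cases(co))
  # printed rounding convention at the reference cohort scale
  expect_equal(round_half_up(100 * 251 / 2249, 1), 11.2)
  expect_equal(round_half_up(100 * 249 / 2249, 1), 11.1)
  # single-cluster cohort is 100.0%
  co2 <- cohort_from_matrices(rep(list(m), 6))
  cl2 <- cluster_cases(rbind(matrix(0, 6, 2)), k = 1, min_size = 1)
  expect_equal(cmt_distribution(cl2, co2)$percent[1], 100.0)
})

test_that("cluster_agreement finds the optimal label matching", {
  truth <- c(1, 1, 1, 2, 2, 2, 3, 3, 3)
  pred <- c(2, 2, 2, 3, 3, 3, 1, 1, 1) # pure relabelling
  expect_equal(cluster_agreement(truth, pred), 1)
  pred2 <- c(2, 2, 1, 3, 3, 3, 1, 1, 1)
  expect_equal(cluster_agreement(truth, pred2), 8 / 9)
})
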