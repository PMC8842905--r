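# Symmetric two-class fixture with class means (0,0) and (10,0) and an
# isotropic pooled covariance: the closed-form LDA boundary is x = 5.
two_class_fixture <- function() {
  blob <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  X <- rbind(blob, sweep(blob, 2, c(10, 0), `+`))
  colnames(X) <- c("x1", "x2")
  list(X = X, y = rep(1:2, each = 4))
}

test_that("two-class model reproduces the closed-form boundary x = 5", {
  f <- two_class_fixture()
  m <- fit_discriminant(f$X, f$y, lambda = 0, priors = "equal")
  r <- classify_cases(m, rbind(c(x1 = 2, x2 = 0)))
  expect_identical(r$class, "1")
  expect_gt(r$scores[1, "1"], r$scores[1, "2"])
  expect_identical(classify_cases(m, rbind(c(x1 = 7, x2 = 0)))$class, "2")
  # exactly on the boundary: equal scores, tie broken toward the lower id
  rb <- classify_cases(m, rbind(c(x1 = 5, x2 = 0)))
  expect_equal(unname(rb$scores[1, "1"]), unname(rb$scores[1, "2"]), tolerance = 1e-9)
  expect_identical(rb$class, "1")
})

test_that("classify agrees with a brute-force minimum-Mahalanobis oracle", {
  set.seed(101)
  for (rep in 1:100) {
    g <- 2 + rep %% 3
    n_per <- 8
    centers <- matrix(rnorm(g * 3, sd = 6), g, 3)
    X <- do.call(rbind, lapply(seq_len(g), function(k) {
      sweep(matrix(rnorm(n_per * 3), n_per, 3), 2, centers[k, ], `+`)
    }))
    colnames(X) <- paste0("v", 1:3)
    y <- rep(seq_len(g), each = n_per)
    m <- fit_discriminant(X, y, lambda = 0, priors = "equal")
    # independent oracle: argmin Mahalanobis distance to the class means
    # under the pooled within-class covariance
    mus <- t(vapply(seq_len(g), function(k) colMeans(X[y == k, ]), numeric(3)))
    W <- Reduce(`+`, lapply(seq_len(g), function(k) {
      Z <- scale(X[y == k, ], center = TRUE, scale = FALSE)
      crossprod(Z)
    })) / (nrow(X) - g)
    Winv <- solve(W)
    probe <- matrix(rnorm(15, sd = 8), 5, 3)
    colnames(probe) <- colnames(X)
    oracle <- apply(probe, 1, function(x) {
      which.min(vapply(seq_len(g), function(k) {
        d <- x - mus[k, ]
        as.numeric(t(d) %*% Winv %*% d)
      }, 0))
    })
    expect_identical(classify_cases(m, probe)$class, as.character(oracle))
  }
})

test_that("selection = none keeps every feature; equations export as text", {
  f <- two_class_fixture()
  m <- fit_discriminant(f$X, f$y, selection = "none")
  expect_identical(m$variables, c("x1", "x2"))
  eq <- export_equations(m)
  expect_length(eq, 2L)
  expect_match(eq[1], "^Y_1 = ")
  expect_match(eq[1], "x1")
  expect_equal(sum(m$priors), 1)
})

test_that("stepwise Wilks selection keeps informative variables, drops noise", {
  set.seed(55)
  n <- 60
  y <- rep(1:2, each = n / 2)
  X <- cbind(sig1 = rnorm(n) + 4 * (y == 2),
             sig2 = rnorm(n) - 3 * (y == 2),
             matrix(rnorm(n * 6), n, 6,
                    dimnames = list(NULL, paste0("noise", 1:6))))
  m <- fit_discriminant(X, y, selection = "stepwise")
  expect_true(all(c("sig1", "sig2") %in% m$variables))
  expect_lt(length(m$variables), 8L)
})

test_that("degenerate fits fail with informative errors", {
  f <- two_class_fixture()
  expect_error(fit_discriminant(f$X, rep(1, 8)), class = "fit_error")
  expect_error(fit_discriminant(f$X, c(1, 1, 1, 1, 1, 1, 1, 2)), class = "fit_error")
  # collinear features with lambda = 0 hit a singular pooled covariance
  Xs <- cbind(f$X, x3 = f$X[, 1])
  expect_error(fit_discriminant(Xs, f$y, lambda = 0), class = "numerical_error")
  expect_s3_class(fit_discriminant(Xs, f$y, lambda = 1e-6), "ceph_lda")
  expect_error(classify_cases(fit_discriminant(f$X, f$y), rbind(c(x1 = 1))),
               class = "classification_error")
})

test_that("LOO separates perfectly separated blobs and zeroes out n = 2", {
  set.seed(77)
  n <- 20
  X <- rbind(matrix(rnorm(n * 2, 0, 1), n, 2),
             matrix(rnorm(n * 2, 40, 1), n, 2)) # separation 40 x SD
  colnames(X) <- c("a", "b")
  y <- rep(1:2, each = n)
  cv <- cross_validate_loo(X, y)
  expect_equal(cv$loo_accuracy, 1.0)
  # two cases, one per class: each fold must assign the other's class
  X2 <- rbind(c(a = 0, b = 0), c(a = 1, b = 1))
  expect_equal(cross_validate_loo(X2, c(1, 2))$loo_accuracy, 0)
})

test_that("LOO accuracy sits at the binomial null for shuffled labels", {
  set.seed(202)
  hits <- 0L
  runs <- 10L
  for (i in seq_len(runs)) {
    X <- matrix(rnorm(200 * 4), 200, 4)
    colnames(X) <- paste0("v", 1:4)
    y <- sample(rep(1:2, each = 100))
    acc <- cross_validate_loo(X, y)$loo_accuracy
    hits <- hits + (acc >= 0.35 && acc <= 0.65)
  }
  expect_gte(hits, runs - 1L)
})

test_that("identical class distributions score at the majority prior", {
  set.seed(91)
  X <- matrix(rnorm(120 * 2), 120, 2)
  colnames(X) <- c("a", "b")
  y <- rep(1:2, c(90, 30)) # signal-free labels, priors 0.75 / 0.25
  m <- fit_discriminant(X, y)
  expect_lt(abs(m$training_summary$resubstitution_accuracy - 0.75), 0.1)
})

test_that("argmax is invariant under a constant feature shift when refit", {
  set.seed(33)
  X <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, c("u", "v", "w")))
  y <- rep(1:3, each = 20)
  X[y == 2, 1] <- X[y == 2, 1] + 3
  X[y == 3, 2] <- X[y == 3, 2] - 3
  m1 <- fit_discriminant(X, y)
  Xs <- X + 100
  m2 <- fit_discriminant(Xs, y)
  expect_identical(classify_cases(m1, X)$class, classify_cases(m2, Xs)$class)
})

test_that("resubstitution accuracy dominates LOO accuracy on average", {
  set.seed(404)
  gaps <- replicate(20, {
    X <- matrix(rnorm(40 * 6), 40, 6)
    colnames(X) <- paste0("v", 1:6)
    y <- rep(1:2, each = 20)
    X[y == 2, 1] <- X[y == 2, 1] + 1.2
    cv <- cross_validate_loo(X, y)
    cv$resubstitution_accuracy - cv$loo_accuracy
  })
  expect_gte(mean(gaps), 0)
})

test_that("implementation matches the reference LDA posterior ranking", {
  skip_if_not_installed("MASS")
  set.seed(61)
  X <- matrix(rnorm(90 * 3), 90, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(1:3, each = 30)
  X[y == 2, 1] <- X[y == 2, 1] + 2.5
  X[y == 3, 3] <- X[y == 3, 3] - 2.5
  ours <- classify_cases(fit_discriminant(X, y, lambda = 0, priors = "equal"), X)$class
  ref <- as.character(predict(MASS::lda(X, grouping = factor(y),
                                        prior = rep(1 / 3, 3)))$class)
  expect_identical(ours, ref)
})
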