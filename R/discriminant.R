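# Linear discriminant classification functions on coordinate features:
# per-class linear score functions Y_g = a0_g + a_g . x (Fisher/SPSS
# "classification function" form), optional Wilks'-lambda stepwise variable
# selection, and leave-one-out cross-validation.

pooled_within_cov <- function(X, g) {
  n <- nrow(X)
  lev <- levels(g)
  W <- matrix(0, ncol(X), ncol(X))
  for (l in lev) {
    Xl <- X[g == l, , drop = FALSE]
    Xl <- sweep(Xl, 2, colMeans(Xl))
    W <- W + crossprod(Xl)
  }
  W / (n - length(lev))
}

wilks_lambda <- function(X, g) {
  # det(W)/det(T) on the given columns
  if (ncol(X) == 0L) return(1)
  lev <- levels(g)
  W <- matrix(0, ncol(X), ncol(X))
  for (l in lev) {
    Xl <- X[g == l, , drop = FALSE]
    Xl <- sweep(Xl, 2, colMeans(Xl))
    W <- W + crossprod(Xl)
  }
  Tt <- sweep(X, 2, colMeans(X))
  Tm <- crossprod(Tt)
  dW <- determinant(W, logarithm = TRUE)
  dT <- determinant(Tm, logarithm = TRUE)
  exp(as.numeric(dW$modulus - dT$modulus))
}

stepwise_wilks <- function(X, g, f_enter = 3.84, f_remove = 2.71,
                           max_steps = 200L) {
  n <- nrow(X)
  ng <- nlevels(g)
  selected <- character(0)
  pool <- colnames(X)
  lam_cur <- 1
  for (step in seq_len(max_steps)) {
    p <- length(selected)
    # entry
    cand <- setdiff(pool, selected)
    if (length(cand)) {
      lams <- vapply(cand, function(v) {
        wilks_lambda(X[, c(selected, v), drop = FALSE], g)
      }, 0)
      fs <- ((n - ng - p) / (ng - 1)) * (lam_cur / lams - 1)
      best <- which.max(fs)
      if (is.finite(fs[best]) && fs[best] >= f_enter) {
        selected <- c(selected, cand[best])
        lam_cur <- lams[best]
      } else cand <- character(0)
    }
    # removal
    removed <- TRUE
    while (removed && length(selected) > 1L) {
      removed <- FALSE
      p <- length(selected)
      lams_wo <- vapply(selected, function(v) {
        wilks_lambda(X[, setdiff(selected, v), drop = FALSE], g)
      }, 0)
      fr <- ((n - ng - p + 1) / (ng - 1)) * (lams_wo / lam_cur - 1)
      worst <- which.min(fr)
      if (is.finite(fr[worst]) && fr[worst] < f_remove) {
        lam_cur <- lams_wo[worst]
        selected <- setdiff(selected, selected[worst])
        removed <- TRUE
      }
    }
    if (!length(cand)) break
  }
  selected
}

#' Fit per-class linear discriminant score functions
#'
#' Classification-function linear discriminant analysis: for class g with
#' mean vector mu_g and pooled within-class covariance S (optionally ridge-
#' regularized as S + lambda * mean(diag(S)) * I), the score coefficients are
#' a_g = S^-1 mu_g with intercept a0_g = -1/2 mu_g' S^-1 mu_g + log(prior_g).
#' A new case is assigned to the class with the largest score. Optional
#' SPSS-style stepwise variable selection greedily minimizes Wilks' lambda
#' with partial-F entry/removal thresholds.
#'
#' @param features `ceph_features`, or numeric matrix with named columns.
#' @param labels class labels (CMT ids), one per row; each class needs >= 2
#'   members.
#' @param selection `"none"` (keep all columns) or `"stepwise"`.
#' @param lambda ridge regularization multiplier (default 1e-6; the actual
#'   ridge added is `lambda * mean(diag(S))`). `lambda = 0` requires a
#'   nonsingular pooled covariance.
#' @param priors `"proportional"` (class shares; default), `"equal"`, or a
#'   named numeric vector summing to 1.
#' @param f_enter,f_remove partial-F thresholds for stepwise selection
#'   (SPSS defaults 3.84 / 2.71).
#' @return a `ceph_lda` model: classes, selected `variables`, per-class
#'   `coefficients` (intercept + slopes), `priors`, and a
#'   `training_summary` with the resubstitution confusion matrix and
#'   accuracy.
#' @export
fit_discriminant <- function(features, labels, selection = c("none", "stepwise"),
                             lambda = 1e-6, priors = "proportional",
                             f_enter = 3.84, f_remove = 2.71) {
  selection <- match.arg(selection)
  X <- if (inherits(features, "ceph_features")) features$X else as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  g <- factor(labels)
  if (nlevels(g) < 2L) stop_ceph("need at least 2 classes", class = "fit_error")
  szs <- table(g)
  if (any(szs < 2L)) {
    stop_ceph("classes with < 2 members: ",
              paste(names(szs)[szs < 2L], collapse = ", "), class = "fit_error")
  }
  vars <- if (selection == "stepwise") {
    stepwise_wilks(X, g, f_enter = f_enter, f_remove = f_remove)
  } else colnames(X)
  if (!length(vars)) stop_ceph("stepwise selection retained no variables", class = "fit_error")
  if (nrow(X) <= length(vars)) {
    warning("fewer cases than selected variables + 1; coefficients may be unstable")
  }
  model <- .lda_core(X[, vars, drop = FALSE], g, lambda = lambda, priors = priors)
  model$selection <- selection
  model$f_enter <- f_enter
  model$f_remove <- f_remove
  # resubstitution
  pred <- classify_cases(model, X)$class
  cm <- table(truth = g, predicted = factor(pred, levels = levels(g)))
  model$training_summary <- list(
    resubstitution_accuracy = mean(pred == as.character(g)),
    confusion = cm)
  model
}

.lda_core <- function(X, g, lambda = 1e-6, priors = "proportional") {
  lev <- levels(g)
  p <- ncol(X)
  n <- nrow(X)
  if (identical(priors, "proportional")) {
    pri <- as.numeric(table(g)) / n
  } else if (identical(priors, "equal")) {
    pri <- rep(1 / length(lev), length(lev))
  } else {
    pri <- as.numeric(priors[lev])
    if (abs(sum(pri) - 1) > 1e-8) stop_ceph("priors must sum to 1", class = "fit_error")
  }
  names(pri) <- lev
  S <- pooled_within_cov(X, g)
  if (lambda > 0) S <- S + lambda * mean(diag(S)) * diag(p)
  mus <- vapply(lev, function(l) colMeans(X[g == l, , drop = FALSE]), numeric(p))
  dim(mus) <- c(p, length(lev))
  A <- tryCatch(
    solve(S, mus), # p x g matrix of a_g columns
    error = function(e) stop_ceph(
      "pooled covariance is singular; refit with lambda > 0",
      class = "numerical_error"))
  a0 <- -0.5 * colSums(mus * A) + log(pri)
  structure(
    list(classes = lev, variables = colnames(X),
         coefficients = rbind(intercept = a0, A),
         priors = pri, lambda = lambda),
    class = "ceph_lda")
}

#' @export
print.ceph_lda <- function(x, ...) {
  cat(sprintf("<ceph_lda> %d classes, %d variables (selection: %s)\n",
              length(x$classes), length(x$variables), x$selection %||% "none"))
  if (!is.null(x$training_summary)) {
    cat(sprintf("  resubstitution accuracy: %.3f\n",
                x$training_summary$resubstitution_accuracy))
  }
  invisible(x)
}

#' Classify cases with a fitted discriminant model
#'
#' Computes every class score Y_g = a0_g + sum(a_g * x) and assigns each case
#' to the argmax; exact ties go to the class with the lower id.
#'
#' @param model a `ceph_lda`.
#' @param newdata numeric matrix (or `ceph_features`) containing at least the
#'   model's variables as named columns; a bare named vector is accepted for
#'   a single case.
#' @return list with `class` (character vector) and `scores` (n x g matrix of
#'   discriminant values).
#' @export
classify_cases <- function(model, newdata) {
  X <- if (inherits(newdata, "ceph_features")) newdata$X else newdata
  if (is.null(dim(X))) X <- matrix(X, 1, dimnames = list(NULL, names(X)))
  miss <- setdiff(model$variables, colnames(X))
  if (length(miss)) {
    stop_ceph("missing model variables: ", paste(miss, collapse = ", "),
              class = "classification_error")
  }
  Xv <- X[, model$variables, drop = FALSE]
  scores <- cbind(1, Xv) %*% model$coefficients
  colnames(scores) <- model$classes
  idx <- max.col(scores, ties.method = "first") # classes ordered by id
  list(class = model$classes[idx], scores = scores)
}

#' Leave-one-out cross-validation of the discriminant model
#'
#' Refits the model with each case held out and classifies the held-out case.
#' By default the variable set selected on the full fit is kept frozen inside
#' the loop (selection outside the loop, the common SPSS usage); with
#' `nested = TRUE` stepwise selection is re-run in every fold.
#'
#' @inheritParams fit_discriminant
#' @param nested re-run stepwise selection within each fold.
#' @return list with `loo_accuracy`, `per_class_recall`, `confusion`,
#'   `resubstitution_accuracy`, and the full-fit `model`.
#' @export
cross_validate_loo <- function(features, labels, selection = c("none", "stepwise"),
                               lambda = 1e-6, priors = "proportional",
                               f_enter = 3.84, f_remove = 2.71, nested = FALSE) {
  selection <- match.arg(selection)
  X <- if (inherits(features, "ceph_features")) features$X else as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  g <- factor(labels)
  full <- if (all(table(g) >= 2L)) {
    fit_discriminant(X, g, selection = selection, lambda = lambda,
                     priors = priors, f_enter = f_enter, f_remove = f_remove)
  } else {
    # singleton classes admit no full fit; LOO still runs fold by fold
    list(variables = colnames(X),
         training_summary = list(resubstitution_accuracy = NA_real_))
  }
  n <- nrow(X)
  pred <- character(n)
  for (i in seq_len(n)) {
    gi <- droplevels(g[-i])
    Xi <- X[-i, , drop = FALSE]
    tb <- table(gi)
    if (sum(tb >= 2L) < 2L) {
      # degenerate fold (e.g. n = 2 with one case per class): assign the
      # largest remaining class (ties to the lower class id)
      pred[i] <- names(tb)[which.max(tb)]
      next
    }
    if (any(tb < 2L)) {
      # singleton classes left behind by the held-out case cannot be
      # refitted; classify among the classes that can
      keep <- gi %in% names(tb)[tb >= 2L]
      gi <- droplevels(gi[keep])
      Xi <- Xi[keep, , drop = FALSE]
    }
    vars_i <- if (nested && selection == "stepwise") {
      stepwise_wilks(Xi, gi, f_enter = f_enter, f_remove = f_remove)
    } else full$variables
    if (!length(vars_i)) vars_i <- full$variables
    m_i <- .lda_core(Xi[, vars_i, drop = FALSE], gi, lambda = lambda, priors = priors)
    pred[i] <- classify_cases(m_i, X[i, , drop = FALSE])$class
  }
  cm <- table(truth = g, predicted = factor(pred, levels = levels(g)))
  recall <- diag(cm) / rowSums(cm)
  list(loo_accuracy = mean(pred == as.character(g)),
       per_class_recall = recall,
       confusion = cm,
       resubstitution_accuracy = full$training_summary$resubstitution_accuracy,
       model = full)
}

#' Export discriminant equations as text
#'
#' One line per class: `Y_<class> = a0 + a1*<var> + ...`.
#'
#' @param model a `ceph_lda`.
#' @param digits significant digits.
#' @return character vector of equations.
#' @export
export_equations <- function(model, digits = 6) {
  vapply(seq_along(model$classes), function(j) {
    co <- model$coefficients[, j]
    terms <- sprintf("%+.*g*%s", digits, co[-1], model$variables)
    sprintf("Y_%s = %.*g %s", model$classes[j], digits, co[1],
            paste(terms, collapse = " "))
  }, "")
}
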