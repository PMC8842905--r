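# Clustering of registered coordinate vectors into morphology groups and
# construction of mean-coordinate templates (CMTs).

#' Build the clustering feature matrix from a registered cohort
#'
#' Concatenates each case's registered coordinates into a row vector
#' (`<code>_x`, `<code>_y` columns, mm) and drops the frame-fixed constant
#' columns (S_x, S_y, N_y are pinned by registration; any other column with
#' variance below 1e-12 is dropped too, and recorded). Cases missing any
#' schema landmark are rejected.
#'
#' @param cohort a registered `ceph_cohort`.
#' @return a `ceph_features` object: list with `X` (n x p matrix, p = 117 for
#'   the full 60-landmark schema), `case_ids`, `dropped` (names of removed
#'   constant columns).
#' @export
build_features <- function(cohort) {
  if (!isTRUE(cohort$registered)) {
    stop_ceph("cohort must be registered", class = "contract_error")
  }
  n <- n_cases(cohort)
  if (n < 2L) stop_ceph("clustering needs at least 2 cases", class = "contract_error")
  codes <- dimnames(cohort$coords)[[1]]
  bad <- which(apply(cohort$coords, 3, anyNA))
  if (length(bad)) {
    cnd <- errorCondition(
      paste0("cases with missing landmarks rejected: ",
             paste(cohort$meta$case_id[bad], collapse = ", ")),
      class = c("missing_landmarks", "cephmorph_error"),
      rejected = cohort$meta$case_id[bad])
    stop(cnd)
  }
  X <- cbind(t(cohort$coords[, 1, ]), t(cohort$coords[, 2, ]))
  colnames(X) <- c(paste0(codes, "_x"), paste0(codes, "_y"))
  # interleave to the conventional x1,y1,x2,y2,... order
  ord <- as.vector(rbind(seq_along(codes), seq_along(codes) + length(codes)))
  X <- X[, ord, drop = FALSE]
  v <- apply(X, 2, stats::var)
  frame_fixed <- c("S_x", "S_y", "N_y")
  drop <- union(frame_fixed, colnames(X)[v <= 1e-12])
  keep <- setdiff(colnames(X), drop)
  structure(list(X = X[, keep, drop = FALSE],
                 case_ids = cohort$meta$case_id,
                 dropped = drop),
            class = "ceph_features")
}

#' @export
print.ceph_features <- function(x, ...) {
  cat(sprintf("<ceph_features> %d cases x %d coordinate variables (%d constant columns dropped)\n",
              nrow(x$X), ncol(x$X), length(x$dropped)))
  invisible(x)
}

mean_silhouette <- function(assign, d) {
  sil <- cluster::silhouette(assign, dist = d)
  mean(sil[, "sil_width"])
}

#' Cluster landmark configurations into morphology groups
#'
#' Clusters the rows of a feature matrix with Ward's criterion on Euclidean
#' distances in mm (no standardization: all coordinates share the mm scale)
#' or with restarted k-means. `k = "auto"` selects the number of clusters in
#' `[2, k_max]` by maximum mean silhouette width. Clusters smaller than
#' `min_size` are pruned: their members become "unclassed" and the surviving
#' clusters are renumbered 1..K by descending size.
#'
#' @param features a `ceph_features` object (or a plain numeric matrix).
#' @param method `"ward"` (agglomerative, Ward/Euclidean) or `"kmeans"`.
#' @param k integer number of clusters, or `"auto"`.
#' @param k_max upper bound for automatic k selection (default 40).
#' @param min_size minimum surviving cluster size (default 5).
#' @param seed integer seed for the k-means restarts (ignored for ward,
#'   which is deterministic given the input order).
#' @return a `ceph_clusters` model: raw assignments, pruning record, CMT
#'   labels (`NA` for unclassed cases), sizes, silhouette profile, and the
#'   hclust merge history in ward mode.
#' @export
cluster_cases <- function(features, method = c("ward", "kmeans"), k = "auto",
                          k_max = 40L, min_size = 5L, seed = NULL) {
  method <- match.arg(method)
  X <- if (inherits(features, "ceph_features")) features$X else as.matrix(features)
  ids <- if (inherits(features, "ceph_features")) features$case_ids else rownames(X) %||% as.character(seq_len(nrow(X)))
  n <- nrow(X)
  if (n < 2L) stop_ceph("clustering needs n >= 2", class = "parameter_error")
  if (is.numeric(k) && (k < 1L || k > n)) {
    stop_ceph("k must be between 1 and n = ", n, class = "parameter_error")
  }

  d <- stats::dist(X)
  degenerate <- ncol(X) == 0L || !all(is.finite(d)) || max(d) < 1e-9
  sil_profile <- NULL
  hc <- NULL

  if (degenerate) {
    raw <- rep(1L, n)
    k_raw <- 1L
  } else if (method == "ward") {
    hc <- stats::hclust(d, method = "ward.D2")
    if (identical(k, "auto")) {
      ks <- 2:min(k_max, n - 1L)
      sil <- vapply(ks, function(kk) mean_silhouette(stats::cutree(hc, kk), d), 0)
      sil_profile <- data.frame(k = ks, mean_silhouette = sil)
      k_raw <- ks[which.max(sil)]
    } else k_raw <- as.integer(k)
    raw <- stats::cutree(hc, k_raw)
  } else {
    if (!is.null(seed)) set.seed(seed)
    run_km <- function(kk) stats::kmeans(X, centers = kk, nstart = 10L, iter.max = 100L)
    if (identical(k, "auto")) {
      ks <- 2:min(k_max, n - 1L)
      fits <- lapply(ks, run_km)
      sil <- vapply(fits, function(f) mean_silhouette(f$cluster, d), 0)
      sil_profile <- data.frame(k = ks, mean_silhouette = sil)
      best <- which.max(sil)
      k_raw <- ks[best]
      raw <- fits[[best]]$cluster
    } else {
      k_raw <- as.integer(k)
      raw <- if (k_raw == 1L) rep(1L, n) else run_km(k_raw)$cluster
    }
  }

  sizes <- table(raw)
  pruned <- as.integer(names(sizes)[sizes < min_size])
  survivors <- as.integer(names(sizes)[sizes >= min_size])
  # renumber survivors by descending size (ties: lower raw id first)
  ordsv <- survivors[order(-as.integer(sizes[as.character(survivors)]), survivors)]
  cmt_of_raw <- stats::setNames(rep(NA_integer_, length(sizes)), names(sizes))
  cmt_of_raw[as.character(ordsv)] <- seq_along(ordsv)
  cmt <- unname(cmt_of_raw[as.character(raw)])

  structure(
    list(method = method, k_raw = k_raw,
         assignments = stats::setNames(raw, ids),
         cmt = stats::setNames(cmt, ids),
         pruned = pruned,
         unclassed = ids[is.na(cmt)],
         n_cmt = length(ordsv),
         cmt_sizes = stats::setNames(as.integer(sizes[as.character(ordsv)]), seq_along(ordsv)),
         min_size = as.integer(min_size),
         silhouette = sil_profile,
         linkage = hc,
         seed = seed),
    class = "ceph_clusters"
  )
}

#' @export
print.ceph_clusters <- function(x, ...) {
  cat(sprintf("<ceph_clusters> %s, k_raw = %d -> %d CMTs (min size %d), %d unclassed\n",
              x$method, x$k_raw, x$n_cmt, x$min_size, length(x$unclassed)))
  invisible(x)
}

#' Build mean-coordinate templates from a cluster model
#'
#' One template per surviving CMT: the coordinate-wise arithmetic mean of the
#' member configurations (which stays in the registered frame: template
#' S = (0,0) and N on the x-axis), with the measurement catalog evaluated on
#' the mean geometry.
#'
#' @param model a `ceph_clusters` fitted on `cohort`.
#' @param cohort the registered `ceph_cohort` the model was fitted on.
#' @param catalog measurement catalog for the template geometry.
#' @return list of `ceph_template` objects (fields `cmt_id`, `n`,
#'   `mean_coords`, `mean_measurements`, `description`).
#' @export
make_templates <- function(model, cohort, catalog = default_catalog()) {
  if (!identical(names(model$cmt), cohort$meta$case_id)) {
    stop_ceph("model was not fitted on this cohort", class = "contract_error")
  }
  lapply(seq_len(model$n_cmt), function(g) {
    idx <- which(!is.na(model$cmt) & model$cmt == g)
    mc <- apply(cohort$coords[, , idx, drop = FALSE], c(1, 2), mean)
    dimnames(mc) <- list(dimnames(cohort$coords)[[1]], c("x", "y"))
    structure(list(cmt_id = g, n = length(idx), mean_coords = mc,
                   mean_measurements = measure_case(mc, catalog),
                   description = NULL),
              class = "ceph_template")
  })
}

#' @export
print.ceph_template <- function(x, ...) {
  cat(sprintf("<ceph_template> CMT %s (n = %d)%s\n", x$cmt_id, x$n,
              if (!is.null(x$description)) paste0(": ", x$description) else ""))
  invisible(x)
}

#' Tabulate the CMT distribution of a clustered cohort
#'
#' @param model a `ceph_clusters`.
#' @param cohort the cohort the model was fitted on (metadata source).
#' @return data.frame with one row per CMT plus an `unclassed` and a `total`
#'   row: member count, percentage (half-up, one decimal), sex counts and
#'   mean age.
#' @export
cmt_distribution <- function(model, cohort) {
  meta <- cohort$meta
  total <- nrow(meta)
  grp <- ifelse(is.na(model$cmt), "unclassed", paste0("CMT_", model$cmt))
  lev <- c(paste0("CMT_", seq_len(model$n_cmt)), "unclassed")
  rows <- lapply(lev, function(g) {
    sel <- grp == g
    data.frame(cmt = g, n = sum(sel),
               percent = round_half_up(100 * sum(sel) / total, 1),
               male = sum(meta$sex[sel] == "male"),
               female = sum(meta$sex[sel] == "female"),
               mean_age = if (any(sel)) round_half_up(mean(meta$age[sel], na.rm = TRUE), 1) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(
    cmt = "total", n = total, percent = round_half_up(100, 1),
    male = sum(meta$sex == "male"), female = sum(meta$sex == "female"),
    mean_age = round_half_up(mean(meta$age, na.rm = TRUE), 1),
    stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Best-match agreement between two partitions
#'
#' Fraction of cases on which a predicted clustering agrees with a reference
#' labelling after optimally matching cluster labels (exact assignment search
#' for up to 10 clusters, greedy beyond).
#'
#' @param truth,pred integer/factor vectors of equal length.
#' @return agreement fraction in \[0, 1\].
#' @export
cluster_agreement <- function(truth, pred) {
  truth <- as.integer(factor(truth))
  pred <- as.integer(factor(pred))
  kt <- max(truth)
  kp <- max(pred)
  tab <- matrix(0L, kt, kp)
  for (i in seq_along(truth)) tab[truth[i], pred[i]] <- tab[truth[i], pred[i]] + 1L
  if (kp <= 10L && kt <= 10L) {
    best <- 0L
    # exact search over injective label matchings (rows -> columns)
    rec <- function(r, used, acc) {
      if (r > kt) { best <<- max(best, acc); return() }
      if (acc + sum(apply(tab[r:kt, , drop = FALSE], 1, max)) <= best) return()
      for (cc in seq_len(kp)) {
        if (!used[cc]) {
          used[cc] <- TRUE
          rec(r + 1L, used, acc + tab[r, cc])
          used[cc] <- FALSE
        }
      }
      if (kp < kt) rec(r + 1L, used, acc) # row left unmatched
    }
    rec(1L, rep(FALSE, kp), 0L)
    best / length(truth)
  } else {
    # greedy fallback
    acc <- 0L
    t2 <- tab
    for (i in seq_len(min(kt, kp))) {
      w <- which(t2 == max(t2), arr.ind = TRUE)[1, ]
      acc <- acc + t2[w[1], w[2]]
      t2[w[1], ] <- -1L
      t2[, w[2]] <- -1L
    }
    acc / length(truth)
  }
}
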