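# Ingest: landmark file reading, triple-digitization calibration,
# magnification correction and rigid registration into the S-origin frame.

#' Calibrate one landmark from its digitization replicates
#'
#' Averages 1-3 digitization replicates of a landmark and applies the
#' triple-digitization quality rule: with exactly three replicates the
#' landmark is flagged for recalibration when the maximum pairwise distance
#' exceeds twice the minimum pairwise distance (strict inequality). With
#' fewer than three replicates the flag is always `FALSE`. Degenerate cases:
#' if all three replicates coincide (max pairwise distance below 1e-9) the
#' flag is `FALSE`; if only the minimum distance is below 1e-9 the ratio is
#' treated as infinite and the flag is `TRUE`.
#'
#' @param replicates numeric matrix with 1-3 rows and 2 columns (x, y), in
#'   image units.
#' @param case,landmark identifiers used in error messages.
#' @return list with `point` (the replicate mean, length-2) and `flag`
#'   (logical recalibration flag).
#' @examples
#' calibrate_landmark(rbind(c(0, 0), c(1, 0), c(3, 0)))$flag # TRUE: 3 > 2*1
#' calibrate_landmark(rbind(c(0, 0), c(1, 0), c(2, 0)))$flag # FALSE: 2 = 2*1
#' @export
calibrate_landmark <- function(replicates, case = "?", landmark = "?") {
  replicates <- rbind(replicates)
  m <- nrow(replicates)
  if (m < 1L || m > 3L) {
    stop_ceph("case ", case, ", landmark ", landmark, ": needs 1-3 replicates",
              class = "malformed_input")
  }
  if (anyNA(replicates) || !all(is.finite(replicates))) {
    stop_ceph("case ", case, ", landmark ", landmark, ": non-finite coordinate",
              class = "malformed_input")
  }
  point <- colMeans(replicates)
  flag <- FALSE
  if (m == 3L) {
    d <- c(.norm2(replicates[1, ] - replicates[2, ]),
           .norm2(replicates[1, ] - replicates[3, ]),
           .norm2(replicates[2, ] - replicates[3, ]))
    mx <- max(d)
    mn <- min(d)
    eps <- 1e-9
    flag <- if (mx < eps) FALSE else if (mn < eps) TRUE else mx > 2 * mn
  }
  list(point = point, flag = flag)
}

# Vectorized calibration for the all-triples case.
# reps: array p x 2 x 3 x n. Returns list(points = p x 2 x n, flags = p x n).
calibrate_triples <- function(reps) {
  stopifnot(length(dim(reps)) == 4L, dim(reps)[3] == 3L)
  points <- (reps[, , 1, , drop = FALSE] + reps[, , 2, , drop = FALSE] +
               reps[, , 3, , drop = FALSE])[, , 1, ] / 3
  pd <- function(i, j) {
    dx <- reps[, 1, i, ] - reps[, 1, j, ]
    dy <- reps[, 2, i, ] - reps[, 2, j, ]
    sqrt(dx * dx + dy * dy)
  }
  d12 <- pd(1, 2); d13 <- pd(1, 3); d23 <- pd(2, 3)
  mx <- pmax(d12, d13, d23)
  mn <- pmin(d12, d13, d23)
  eps <- 1e-9
  flags <- ifelse(mx < eps, FALSE, ifelse(mn < eps, TRUE, mx > 2 * mn))
  dim(points) <- c(dim(reps)[1], 2L, dim(reps)[4])
  list(points = points, flags = flags)
}

#' Convert image-unit coordinates to mm
#'
#' Divides coordinates by the scale factor (image units per mm, projection
#' magnification included).
#'
#' @param point numeric point, matrix or array of coordinates in image units.
#' @param scale_factor positive real, image units per mm.
#' @return coordinates in mm.
#' @export
apply_magnification <- function(point, scale_factor) {
  if (!is.numeric(scale_factor) || length(scale_factor) != 1L ||
      !is.finite(scale_factor) || scale_factor <= 0) {
    stop_ceph("scale_factor must be a positive real", class = "configuration_error")
  }
  point / scale_factor
}

# Rigid registration of one p x 2 landmark matrix: S -> (0,0),
# N -> (+|SN|, 0); rotation only (det +1), so the y-down orientation of the
# input image is preserved (+y inferior after registration).
register_matrix <- function(m, case = "?") {
  s <- m["S", ]
  n <- m["N", ]
  if (anyNA(s) || anyNA(n)) {
    stop_ceph("case ", case, ": S and N are required for registration",
              class = "degenerate_frame")
  }
  v <- n - s
  L <- .norm2(v)
  if (L <= 0.1) {
    stop_ceph("case ", case, ": |S-N| = ", format(L), " mm <= 0.1 mm",
              class = "degenerate_frame")
  }
  ct <- v[1] / L
  st <- v[2] / L
  R <- rbind(c(ct, st), c(-st, ct)) # maps v to (L, 0); det = +1
  out <- sweep(m, 2, s) %*% t(R)
  out["S", ] <- c(0, 0)
  out["N", ] <- c(L, 0)
  dimnames(out) <- dimnames(m)
  attr(out, "sn_length") <- L
  out
}

#' Register a cohort into the sella-origin / SN-axis frame
#'
#' Applies, per case, the rigid transform (translation + rotation, no scaling
#' or reflection) that maps sella to the origin and nasion onto the positive
#' x-axis. Inter-landmark distances are preserved exactly (up to floating
#' point); +y remains the inferior direction.
#'
#' @param cohort a `ceph_cohort` in mm (calibrated, image frame or already
#'   registered; registering twice is a no-op up to floating point).
#' @return the registered `ceph_cohort` with `sn_length` filled in.
#' @export
register_cohort <- function(cohort) {
  p <- dim(cohort$coords)[1]
  n <- n_cases(cohort)
  out <- cohort$coords
  sn <- numeric(n)
  for (i in seq_len(n)) {
    m <- register_matrix(cohort$coords[, , i], case = cohort$meta$case_id[i])
    sn[i] <- attr(m, "sn_length")
    out[, , i] <- m
  }
  cohort$coords <- out
  cohort$registered <- TRUE
  cohort$sn_length <- sn
  cohort
}

#' Read a landmark replicate CSV
#'
#' Dialect: header `case_id,landmark,replicate,x,y`, one row per digitization
#' replicate, landmark values are schema codes.
#'
#' @param path file path.
#' @return data.frame in the landmark dialect.
#' @export
read_landmark_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("case_id", "landmark", "replicate", "x", "y")
  if (!identical(names(df)[seq_along(need)], need)) {
    stop_ceph("landmark CSV must have header ", paste(need, collapse = ","),
              class = "malformed_input")
  }
  df
}

#' Write a landmark replicate CSV
#' @param df data.frame in the landmark dialect (see [read_landmark_csv()]).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_landmark_csv <- function(df, path) {
  df$x <- sprintf("%.9f", df$x)
  df$y <- sprintf("%.9f", df$y)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a case metadata CSV
#'
#' Dialect: header `case_id,sex,age,angle_class,treatment,timepoint,scale_factor`.
#'
#' @param path file path.
#' @return data.frame of per-case metadata.
#' @export
read_meta_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("case_id", "sex", "age", "angle_class", "treatment", "timepoint",
            "scale_factor")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_ceph("metadata CSV missing columns: ", paste(miss, collapse = ", "),
              class = "malformed_input")
  }
  df
}

#' Ingest landmark replicates and metadata into a registered cohort
#'
#' Runs the full ingest pipeline: per-landmark replicate averaging with the
#' triple-digitization recalibration flag, magnification correction
#' (division by `scale_factor`), and rigid registration into the
#' sella-origin / SN-axis frame. Landmarks absent from a case are kept as
#' `NA` (never imputed); such cases are rejected later by feature building
#' but still support the measurements their landmarks allow.
#'
#' @param landmarks data.frame in the landmark dialect, or a path to such a
#'   CSV.
#' @param meta data.frame of metadata, or a path to a metadata CSV.
#' @param schema landmark schema.
#' @param register register the cohort (default `TRUE`).
#' @return a `ceph_cohort` (registered unless `register = FALSE`).
#' @export
ingest_cohort <- function(landmarks, meta, schema = ceph_schema(),
                          register = TRUE) {
  if (is.character(landmarks)) landmarks <- read_landmark_csv(landmarks)
  if (is.character(meta)) meta <- read_meta_csv(meta)
  validate_schema(schema)
  if (nrow(meta) == 0L) stop_ceph("empty cohort", class = "empty_input")
  if (anyNA(landmarks$x) || anyNA(landmarks$y) ||
      !all(is.finite(landmarks$x)) || !all(is.finite(landmarks$y))) {
    bad <- which(!is.finite(landmarks$x) | !is.finite(landmarks$y))[1]
    stop_ceph("case ", landmarks$case_id[bad], ", landmark ",
              landmarks$landmark[bad], ": non-finite coordinate",
              class = "malformed_input")
  }
  unknown <- setdiff(unique(landmarks$landmark), schema$code)
  if (length(unknown)) {
    stop_ceph("unknown landmark codes: ", paste(unknown, collapse = ", "),
              class = "malformed_input")
  }
  ids <- meta$case_id
  p <- nrow(schema)
  n <- length(ids)
  cf <- factor(landmarks$case_id, levels = ids)
  if (anyNA(cf)) {
    stop_ceph("landmark rows for cases absent from metadata: ",
              paste(unique(landmarks$case_id[is.na(cf)]), collapse = ", "),
              class = "malformed_input")
  }
  lf <- factor(landmarks$landmark, levels = schema$code)

  pts <- array(NA_real_, c(p, 2, n))
  flags <- matrix(NA, p, n)
  cnt <- table(lf, cf)
  if (all(cnt == 3L)) {
    # fast path: full triples everywhere
    o <- order(cf, lf, landmarks$replicate)
    reps <- array(NA_real_, c(p, 2, 3, n))
    xs <- landmarks$x[o]
    ys <- landmarks$y[o]
    # ordered as replicate fastest within landmark within case
    dim(xs) <- c(3, p, n)
    dim(ys) <- c(3, p, n)
    reps[, 1, , ] <- aperm(xs, c(2, 1, 3))
    reps[, 2, , ] <- aperm(ys, c(2, 1, 3))
    cal <- calibrate_triples(reps)
    pts <- cal$points
    flags <- cal$flags
  } else {
    if (any(cnt > 3L)) {
      stop_ceph("more than 3 replicates for some case/landmark",
                class = "malformed_input")
    }
    sp <- split(seq_len(nrow(landmarks)), list(lf, cf), drop = TRUE)
    for (key in names(sp)) {
      rows <- sp[[key]]
      li <- as.integer(lf[rows[1]])
      ci <- as.integer(cf[rows[1]])
      cal <- calibrate_landmark(cbind(landmarks$x[rows], landmarks$y[rows]),
                                case = ids[ci], landmark = schema$code[li])
      pts[li, , ci] <- cal$point
      flags[li, ci] <- cal$flag
    }
  }

  # magnification correction per case
  for (i in seq_len(n)) {
    pts[, , i] <- apply_magnification(pts[, , i], meta$scale_factor[i])
  }
  cohort <- ceph_cohort(pts, meta, schema = schema, registered = FALSE,
                        recalibrated = flags)
  if (register) cohort <- register_cohort(cohort)
  cohort
}

#' Summarize cohort composition
#'
#' Counts and printed-style percentages (half-up, one decimal) by sex and by
#' Angle class, plus mean and SD of age.
#'
#' @param x a `ceph_cohort` or a metadata data.frame with columns `sex`,
#'   `angle_class` and `age`.
#' @return list with elements `n`, `sex` (data.frame level/count/percent),
#'   `angle_class` (idem), `age_mean`, `age_sd`.
#' @export
summarize_cohort <- function(x) {
  meta <- if (inherits(x, "ceph_cohort")) x$meta else x
  if (is.null(meta) || nrow(meta) == 0L) {
    stop_ceph("empty cohort", class = "empty_input")
  }
  n <- nrow(meta)
  tab <- function(v, levels) {
    v <- factor(v, levels = levels)
    cnt <- as.integer(table(v))
    data.frame(level = levels, count = cnt,
               percent = round_half_up(100 * cnt / n, 1),
               stringsAsFactors = FALSE)
  }
  list(
    n = n,
    sex = tab(meta$sex, c("male", "female", "unknown")),
    angle_class = tab(meta$angle_class, c("I", "II", "III", "unknown")),
    age_mean = mean(meta$age, na.rm = TRUE),
    age_sd = stats::sd(meta$age, na.rm = TRUE)
  )
}

#' Read a TPS landmark file
#'
#' Minimal TPS dialect: `LM=<p>` followed by `p` lines of `x y`, then `ID=`
#' and optionally `SCALE=` per specimen. Coordinates are taken in the file's
#' own axis convention; `SCALE=` maps to `scale_factor` (image units per mm).
#' One replicate per case.
#'
#' @param path file path.
#' @return list with `landmarks` (data.frame in the landmark replicate
#'   dialect, replicate = 1) and `scale` (named numeric of scale factors).
#' @param schema landmark schema used to assign codes, in order.
#' @export
read_tps <- function(path, schema = ceph_schema()) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  scales <- numeric(0)
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^LM=", lines[i])) stop_ceph("TPS: expected LM= line", class = "malformed_input")
    p <- as.integer(sub("^LM=", "", lines[i]))
    xy <- do.call(rbind, lapply(lines[(i + 1):(i + p)], function(l) {
      as.numeric(strsplit(l, "[ \t]+")[[1]][1:2])
    }))
    i <- i + p + 1L
    id <- NA_character_
    sc <- 1
    while (i <= length(lines) && !grepl("^LM=", lines[i])) {
      if (grepl("^ID=", lines[i])) id <- sub("^ID=", "", lines[i])
      if (grepl("^SCALE=", lines[i])) sc <- as.numeric(sub("^SCALE=", "", lines[i]))
      i <- i + 1L
    }
    if (is.na(id)) id <- paste0("specimen_", length(out) + 1L)
    if (p != nrow(schema)) {
      stop_ceph("TPS: LM=", p, " but schema has ", nrow(schema), " landmarks",
                class = "malformed_input")
    }
    out[[id]] <- data.frame(case_id = id, landmark = schema$code,
                            replicate = 1L, x = xy[, 1], y = xy[, 2],
                            stringsAsFactors = FALSE)
    scales[id] <- sc
  }
  list(landmarks = do.call(rbind, c(out, list(make.row.names = FALSE))),
       scale = scales)
}

#' Write a TPS landmark file
#'
#' Writes one TPS block per case (single replicate: the calibrated mean if
#' the cohort was ingested from triples).
#'
#' @param cohort a `ceph_cohort`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- dim(cohort$coords)[1]
  for (i in seq_len(n_cases(cohort))) {
    writeLines(sprintf("LM=%d", p), con)
    writeLines(sprintf("%.9f %.9f", cohort$coords[, 1, i], cohort$coords[, 2, i]), con)
    writeLines(sprintf("ID=%s", cohort$meta$case_id[i]), con)
    writeLines(sprintf("SCALE=%.9f", cohort$meta$scale_factor[i]), con)
  }
  invisible(path)
}
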