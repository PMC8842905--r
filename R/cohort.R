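#' Construct a cephalometric cohort object
#'
#' A cohort holds one digitized timepoint per case: a `p x 2 x n` array of
#' landmark coordinates in mm (landmark codes x (x, y) x cases), the per-case
#' metadata, and per-landmark recalibration flags from the triple-digitization
#' rule. Coordinates are in the image frame until [register_cohort()] moves
#' them into the sella-origin / SN-axis frame.
#'
#' @param coords numeric array `p x 2 x n`, dimnames landmark codes,
#'   `c("x","y")`, case ids. `NA` rows mark landmarks missing for a case.
#' @param meta data.frame with columns `case_id`, `sex`, `age`, `angle_class`,
#'   `treatment`, `timepoint`, `scale_factor` (one row per case, same order as
#'   the third array dimension).
#' @param schema landmark schema, see [ceph_schema()].
#' @param registered logical; `TRUE` once coordinates are in the S-origin
#'   frame.
#' @param sn_length numeric vector of |S-N| per case (mm), for registered
#'   cohorts.
#' @param recalibrated logical `p x n` matrix of triple-digitization
#'   recalibration flags.
#' @return an object of class `ceph_cohort`.
#' @export
ceph_cohort <- function(coords, meta, schema = ceph_schema(),
                        registered = FALSE, sn_length = NULL,
                        recalibrated = NULL) {
  validate_schema(schema)
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 2L)
  if (dim(coords)[1] != nrow(schema)) {
    stop_ceph("coords must have one row per schema landmark", class = "cohort_invalid")
  }
  n <- dim(coords)[3]
  if (nrow(meta) != n) stop_ceph("meta must have one row per case", class = "cohort_invalid")
  dimnames(coords) <- list(schema$code, c("x", "y"), meta$case_id)
  structure(
    list(coords = coords, meta = meta, schema = schema,
         registered = registered,
         sn_length = sn_length,
         recalibrated = recalibrated),
    class = "ceph_cohort"
  )
}

#' Number of cases in a cohort
#' @param x a `ceph_cohort`.
#' @return integer case count.
#' @export
n_cases <- function(x) dim(x$coords)[3]

#' Extract the coordinate array of a cohort
#' @param x a `ceph_cohort`.
#' @return the `p x 2 x n` coordinate array in mm.
#' @export
coords <- function(x) x$coords

#' Extract one case's landmark matrix
#' @param x a `ceph_cohort`.
#' @param i case index or case id.
#' @return a `p x 2` matrix with landmark codes as rownames.
#' @export
case_coords <- function(x, i) {
  m <- x$coords[, , i, drop = TRUE]
  dimnames(m) <- list(dimnames(x$coords)[[1]], c("x", "y"))
  m
}

#' Subset a cohort by case
#' @param x a `ceph_cohort`.
#' @param i logical, integer or character index of cases to keep.
#' @param ... unused.
#' @return a `ceph_cohort` with the selected cases.
#' @export
subset_cases <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$meta$case_id)
  ceph_cohort(x$coords[, , i, drop = FALSE], x$meta[i, , drop = FALSE],
              schema = x$schema, registered = x$registered,
              sn_length = x$sn_length[i],
              recalibrated = if (!is.null(x$recalibrated)) x$recalibrated[, i, drop = FALSE])
}

#' @export
print.ceph_cohort <- function(x, ...) {
  cat(sprintf("<ceph_cohort> %d cases, %d landmarks, %s frame\n",
              n_cases(x), dim(x$coords)[1],
              if (isTRUE(x$registered)) "registered (S-origin/SN-axis)" else "image"))
  if (!is.null(x$recalibrated)) {
    cat(sprintf("  recalibration flags set for %d landmark digitizations\n",
                sum(x$recalibrated, na.rm = TRUE)))
  }
  tp <- table(x$meta$timepoint)
  cat("  timepoints:", paste(sprintf("%s=%d", names(tp), tp), collapse = ", "), "\n")
  invisible(x)
}
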