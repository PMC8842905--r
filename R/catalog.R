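# Declarative measurement catalog: the full 135-name measurement inventory,
# with geometric constructions for the clinically decisive subset. Entries
# without a standard two/three/four-landmark construction are registered by
# name and always evaluate to the not-computable marker (NA).

# Full printed measurement inventory (4-column table flattened row-wise).
# "Ns-Sn" is listed twice in the source table; the second occurrence is kept
# unique as "Ns-Sn (2)".
measurement_names_135 <- function() {
  c("SNA", "SN/OP2", "A-NPg", "Ns-Pos",
    "SNB", "FH/OP1", "U1/NA", "Ns-Sn",
    "ANB", "FH/OP2", "UIE-NA", "NLA(Cm-Sn-UL)",
    "SNPg", "OP1/MP", "U1/PP", "Ns-Mes",
    "NSBa", "OP2/MP", "U1/FH", "Stoms-Stomi",
    "NSAr", "OP2/PP", "ANPr", "Ns-Sn (2)",
    "FH/NA", "OP1/PP", "UIE-AP", "Sn-Stoms",
    "SN/FH", "OPu/PP", "UIE-PP", "Sn-Mes",
    "S-N", "OPl/MP", "UMC-PP", "Stomi-Bs",
    "S-Ba", "L1/OP1", "U1/SN", "Stomi-Mes",
    "Ba-N", "LI/OPL", "L1/NB", "Stoms-UIE",
    "A-NFH", "LI/OP2", "L1/MP", "UIR-UMR",
    "Ptm-S(FH)", "UI/OPu", "LI/FH", "UIR-UMR(PP)",
    "PNS-ANS(FH)", "UI/OP1", "CL/MP", "UIE-UMC",
    "PNS-A(FH)", "UI/OP2", "LIE-AP", "UIA-UMA",
    "Ptm-A(FH)", "LM/OPL", "LIE-MP", "UIA-UMA(PP)",
    "FH/NB", "LM/OP1", "LIE-NB", "LIR-LMR",
    "NGoGn", "LM/OP2", "LMC-MP", "LIR-LMR(MP)",
    "SGoN", "UM/OP1", "U1/L1", "LIE-LMC",
    "MP/SN", "UM/OP2", "UM/LM", "LIA-LMA",
    "MP/FH", "NsPos/FH", "overjet", "LIA-LMA(MP)",
    "NSGn", "S-Ns-Sn", "overbite", "UM/PP",
    "SArGo", "S-Ns-Bs", "UMC-LMC(OP1)", "LM/PP",
    "B-NFH", "Sn-Ns-Bs", "UMC-LMC(OP2)", "Ptm/UMC(FH)",
    "SL", "S-Ns-Pos", "SN/OP1", "SE",
    "AsUL_BsLL", "Co-Gn", "Prn-H", "Co-S(FH)",
    "AsUL-FH", "Sn-H", "Go-Gn", "BsLL-FH",
    "N-Me", "Pg-NB", "Bs-H", "S-Go",
    "PosBs-FH", "ANPg", "LL-H", "S-Go/N-Me",
    "Ns-Prn-Pos", "NA/PA", "UL-EP", "MP/ArGoP",
    "Z angle", "MP/PP", "LL-EP", "Co-Pg(MP)",
    "H angle", "Wits", "UL-SnPos", "ArGoGn",
    "LL-Bs-Pos", "A-B(FH)", "LL-SnPos", "Co-B",
    "Sn-Gns-C", "Co-Pg", "Prn-SnFH")
}

cat_entry <- function(name, primitive, args, units, sign = NULL) {
  list(name = name, primitive = primitive, args = args, units = units,
       sign = sign)
}

# Constructions for the computable subset. Reference-plane choices
# (documented defaults): mandibular plane Go-Me, Frankfort horizontal P-Or,
# functional occlusal plane Interdental-M -> Interdental-I, esthetic line
# Prn -> Pos (oriented superior-to-inferior so anterior is positive).
default_definitions <- function() {
  d <- list(
    cat_entry("SNA",  "angle3", c("S", "N", "A"), "degrees"),
    cat_entry("SNB",  "angle3", c("S", "N", "B"), "degrees"),
    cat_entry("SNPg", "angle3", c("S", "N", "Pg"), "degrees"),
    cat_entry("NSBa", "angle3", c("N", "S", "Ba"), "degrees"),
    cat_entry("NSAr", "angle3", c("N", "S", "Ar"), "degrees"),
    cat_entry("NSGn", "angle3", c("N", "S", "Gn"), "degrees"),
    cat_entry("NGoGn", "angle3", c("N", "Go", "Gn"), "degrees"),
    cat_entry("SGoN", "angle3", c("S", "Go", "N"), "degrees"),
    cat_entry("SArGo", "angle3", c("S", "Ar", "Go"), "degrees"),
    cat_entry("ArGoGn", "angle3", c("Ar", "Go", "Gn"), "degrees"),
    cat_entry("NLA(Cm-Sn-UL)", "angle3", c("Cm", "Sn", "UL"), "degrees"),
    cat_entry("Ns-Prn-Pos", "angle3", c("Ns", "Prn", "Pos"), "degrees"),
    cat_entry("S-Ns-Sn", "angle3", c("S", "Ns", "Sn"), "degrees"),
    cat_entry("S-Ns-Bs", "angle3", c("S", "Ns", "Bs"), "degrees"),
    cat_entry("Sn-Ns-Bs", "angle3", c("Sn", "Ns", "Bs"), "degrees"),
    cat_entry("S-Ns-Pos", "angle3", c("S", "Ns", "Pos"), "degrees"),

    # plane-to-plane angles (undirected)
    cat_entry("MP/SN", "line_line_angle", c("Go", "Me", "S", "N"), "degrees"),
    cat_entry("MP/FH", "line_line_angle", c("Go", "Me", "P", "Or"), "degrees"),
    cat_entry("SN/FH", "line_line_angle", c("S", "N", "P", "Or"), "degrees"),
    cat_entry("FH/NA", "line_line_angle", c("P", "Or", "N", "A"), "degrees"),
    cat_entry("FH/NB", "line_line_angle", c("P", "Or", "N", "B"), "degrees"),
    # Z angle: Frankfort horizontal against the profile line soft
    # pogonion -> upper lip; H angle: H line (Pos-UL) against the soft
    # facial plane Ns-Pos (both as undirected line/line angles).
    cat_entry("Z angle", "line_line_angle", c("P", "Or", "Pos", "UL"), "degrees"),
    cat_entry("H angle", "line_line_angle", c("Pos", "UL", "Ns", "Pos"), "degrees"),

    # directed axis inclinations: ray S->N (or plane analog) against the
    # incisor long axis oriented edge -> apex; upright = 90, proclination
    # > 90, retroclination (linguoclination) < 90.
    cat_entry("U1/SN", "ray_angle", c("S", "N", "UIE", "UIA"), "degrees"),
    cat_entry("U1/NA", "ray_angle", c("N", "A", "UIE", "UIA"), "degrees"),
    cat_entry("L1/MP", "ray_angle", c("Me", "Go", "LIE", "LIA"), "degrees"),
    cat_entry("L1/NB", "ray_angle", c("N", "B", "LIE", "LIA"), "degrees"),
    cat_entry("U1/L1", "ray_angle", c("UIA", "UIE", "LIA", "LIE"), "degrees"),

    # distances
    cat_entry("S-N", "point_point_distance", c("S", "N"), "mm"),
    cat_entry("S-Ba", "point_point_distance", c("S", "Ba"), "mm"),
    cat_entry("Ba-N", "point_point_distance", c("Ba", "N"), "mm"),
    cat_entry("N-Me", "point_point_distance", c("N", "Me"), "mm"),
    cat_entry("S-Go", "point_point_distance", c("S", "Go"), "mm"),
    cat_entry("Co-Gn", "point_point_distance", c("Co", "Gn"), "mm"),
    cat_entry("Co-Pg", "point_point_distance", c("Co", "Pg"), "mm"),
    cat_entry("Go-Gn", "point_point_distance", c("Go", "Gn"), "mm"),
    cat_entry("Co-B", "point_point_distance", c("Co", "B"), "mm"),
    cat_entry("Ns-Pos", "point_point_distance", c("Ns", "Pos"), "mm"),
    cat_entry("Ns-Sn", "point_point_distance", c("Ns", "Sn"), "mm"),
    cat_entry("Ns-Mes", "point_point_distance", c("Ns", "Mes"), "mm"),
    cat_entry("Stoms-Stomi", "point_point_distance", c("Stoms", "Stomi"), "mm"),

    # signed point-to-line distances (line oriented superior -> inferior so
    # the anterior side is positive)
    cat_entry("UL-EP", "point_line_signed_distance", c("UL", "Prn", "Pos"),
              "mm", sign = "anterior positive"),
    cat_entry("LL-EP", "point_line_signed_distance", c("LL", "Prn", "Pos"),
              "mm", sign = "anterior positive"),
    cat_entry("A-NPg", "point_line_signed_distance", c("A", "N", "Pg"),
              "mm", sign = "anterior positive"),
    cat_entry("Pg-NB", "point_line_signed_distance", c("Pg", "N", "B"),
              "mm", sign = "anterior positive"),
    cat_entry("UIE-NA", "point_line_signed_distance", c("UIE", "N", "A"),
              "mm", sign = "anterior positive"),
    cat_entry("LIE-NB", "point_line_signed_distance", c("LIE", "N", "B"),
              "mm", sign = "anterior positive"),
    cat_entry("UIE-AP", "point_line_signed_distance", c("UIE", "A", "Pg"),
              "mm", sign = "anterior positive"),
    cat_entry("LIE-AP", "point_line_signed_distance", c("LIE", "A", "Pg"),
              "mm", sign = "anterior positive"),
    cat_entry("UL-SnPos", "point_line_signed_distance", c("UL", "Sn", "Pos"),
              "mm", sign = "anterior positive"),
    cat_entry("LL-SnPos", "point_line_signed_distance", c("LL", "Sn", "Pos"),
              "mm", sign = "anterior positive"),

    # axis projections
    cat_entry("overjet", "projected_distance", c("UIE", "LIE", "P", "Or"),
              "mm", sign = "UIE anterior of LIE positive"),
    cat_entry("overbite", "normal_projected_distance",
              c("UIE", "LIE", "P", "Or"), "mm",
              sign = "UIE inferior of LIE (incisal overlap) positive"),
    cat_entry("Wits", "projected_distance",
              c("A", "B", "Interdental-M", "Interdental-I"), "mm",
              sign = "A ahead of B along the occlusal plane positive"),
    cat_entry("A-NFH", "projected_distance", c("A", "N", "P", "Or"), "mm",
              sign = "A anterior of the nasion perpendicular positive"),
    cat_entry("B-NFH", "projected_distance", c("B", "N", "P", "Or"), "mm",
              sign = "B anterior of the nasion perpendicular positive"),
    cat_entry("A-B(FH)", "projected_distance", c("A", "B", "P", "Or"), "mm",
              sign = "A anterior of B positive"),

    # derived quantities
    cat_entry("ANB", "derived", c("SNA", "SNB"), "degrees",
              sign = "SNA - SNB, positive when the maxilla leads"),
    cat_entry("S-Go/N-Me", "derived_ratio", c("S-Go", "N-Me"), "percent")
  )
  names(d) <- vapply(d, `[[`, "", "name")
  d
}

#' Build the default measurement catalog
#'
#' The catalog registers the full 135-name printed measurement inventory.
#' Entries with a standard geometric construction (about 60) carry a
#' primitive (`angle3`, `ray_angle`, `line_line_angle`,
#' `point_point_distance`, `point_line_signed_distance`,
#' `projected_distance`, `normal_projected_distance`, or a derived
#' combination) and ordered landmark arguments; the remainder are declared
#' but not computable and always evaluate to `NA`, preserving the inventory
#' without inventing definitions.
#'
#' @param schema landmark schema used to validate argument codes.
#' @return a `ceph_catalog` object (named list of measurement definitions).
#' @export
default_catalog <- function(schema = ceph_schema()) {
  nm <- measurement_names_135()
  defs <- default_definitions()
  entries <- lapply(nm, function(x) {
    defs[[x]] %||% cat_entry(x, "undefined", character(0), "unknown")
  })
  names(entries) <- nm
  validate_catalog(structure(entries, class = "ceph_catalog"), schema)
}

#' Validate a measurement catalog
#'
#' Checks that every primitive's arity matches and every landmark argument is
#' a known schema code.
#'
#' @param catalog a `ceph_catalog`.
#' @param schema landmark schema.
#' @return the catalog, invisibly usable; errors on invalid entries.
#' @export
validate_catalog <- function(catalog, schema = ceph_schema()) {
  arity <- c(angle3 = 3L, ray_angle = 4L, line_line_angle = 4L,
             point_point_distance = 2L, point_line_signed_distance = 3L,
             projected_distance = 4L, normal_projected_distance = 4L,
             derived = 2L, derived_ratio = 2L, undefined = NA)
  for (e in catalog) {
    if (!e$primitive %in% names(arity)) {
      stop_ceph("catalog entry ", e$name, ": unknown primitive ", e$primitive,
                class = "catalog_invalid")
    }
    k <- arity[[e$primitive]]
    if (!is.na(k) && length(e$args) != k) {
      stop_ceph("catalog entry ", e$name, ": primitive ", e$primitive,
                " needs ", k, " arguments", class = "catalog_invalid")
    }
    if (!e$primitive %in% c("derived", "derived_ratio", "undefined") &&
        !all(e$args %in% schema$code)) {
      stop_ceph("catalog entry ", e$name, ": unknown landmark code ",
                paste(setdiff(e$args, schema$code), collapse = ", "),
                class = "catalog_invalid")
    }
  }
  catalog
}

#' @export
print.ceph_catalog <- function(x, ...) {
  comp <- sum(vapply(x, function(e) e$primitive != "undefined", TRUE))
  cat(sprintf("<ceph_catalog> %d measurements (%d computable, %d declared-only)\n",
              length(x), comp, length(x) - comp))
  invisible(x)
}

#' Evaluate the measurement catalog on one landmark configuration
#'
#' @param coords `p x 2` matrix of registered coordinates in mm with landmark
#'   codes as rownames (e.g. from [case_coords()] or a template's mean
#'   geometry).
#' @param catalog a `ceph_catalog`.
#' @return named numeric vector, one value per catalog entry; `NA` is the
#'   not-computable marker (undefined entry or missing landmark).
#' @export
measure_case <- function(coords, catalog = default_catalog()) {
  vals <- stats::setNames(rep(NA_real_, length(catalog)), names(catalog))
  deferred <- list()
  for (e in catalog) {
    if (e$primitive %in% c("derived", "derived_ratio")) {
      deferred[[length(deferred) + 1L]] <- e
      next
    }
    if (e$primitive == "undefined") next
    pts <- coords[e$args, , drop = FALSE]
    if (anyNA(pts)) next
    pl <- lapply(seq_len(nrow(pts)), function(i) pts[i, ])
    vals[e$name] <- switch(
      e$primitive,
      angle3 = angle3(pl[[1]], pl[[2]], pl[[3]], name = e$name),
      ray_angle = ray_angle(pl[[1]], pl[[2]], pl[[3]], pl[[4]], name = e$name),
      line_line_angle = line_line_angle(pl[[1]], pl[[2]], pl[[3]], pl[[4]], name = e$name),
      point_point_distance = point_point_distance(pl[[1]], pl[[2]]),
      point_line_signed_distance = point_line_signed_distance(pl[[1]], pl[[2]], pl[[3]], name = e$name),
      projected_distance = projected_distance(pl[[1]], pl[[2]], pl[[3]], pl[[4]], name = e$name),
      normal_projected_distance = normal_projected_distance(pl[[1]], pl[[2]], pl[[3]], pl[[4]], name = e$name)
    )
  }
  for (e in deferred) {
    a <- vals[e$args[1]]
    b <- vals[e$args[2]]
    if (is.na(a) || is.na(b)) next
    vals[e$name] <- if (e$primitive == "derived") a - b else 100 * a / b
  }
  vals
}

#' Evaluate the catalog over a cohort
#'
#' @param cohort a registered `ceph_cohort`.
#' @param catalog a `ceph_catalog`.
#' @return data.frame with `case_id` and one numeric column per measurement
#'   (`NA` marks not-computable entries).
#' @export
evaluate_cohort <- function(cohort, catalog = default_catalog()) {
  if (!isTRUE(cohort$registered)) {
    stop_ceph("cohort must be registered before measurement", class = "contract_error")
  }
  n <- n_cases(cohort)
  m <- t(vapply(seq_len(n), function(i) measure_case(case_coords(cohort, i), catalog),
                numeric(length(catalog))))
  out <- data.frame(case_id = cohort$meta$case_id, m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a measurement catalog to YAML
#' @param catalog a `ceph_catalog`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_catalog_yaml <- function(catalog, path) {
  yaml::write_yaml(lapply(unclass(catalog), function(e) {
    e[!vapply(e, is.null, TRUE)]
  }), path)
  invisible(path)
}

#' Read a measurement catalog from YAML
#' @param path file path.
#' @param schema landmark schema for validation.
#' @return a `ceph_catalog`.
#' @export
read_catalog_yaml <- function(path, schema = ceph_schema()) {
  raw <- yaml::read_yaml(path)
  entries <- lapply(raw, function(e) {
    cat_entry(e$name, e$primitive, as.character(e$args %||% character(0)),
              e$units %||% "unknown", e$sign)
  })
  names(entries) <- vapply(entries, `[[`, "", "name")
  validate_catalog(structure(entries, class = "ceph_catalog"), schema)
}
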