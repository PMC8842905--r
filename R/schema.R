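#' The 60-landmark cephalometric schema
#'
#' The ordered dictionary of digitized landmarks used throughout the package:
#' 46 hard-tissue and 14 soft-tissue points of the lateral cephalogram, from
#' sella (S) and nasion (N) through the incisor/molar dental points to the
#' soft-tissue profile (Ns ... Mes) and the incisor resistance-centre points.
#'
#' @return a data.frame with columns `index` (1..60), `code` (short landmark
#'   code, unique), `name` (long anatomical name) and `tissue`
#'   (`"hard"`/`"soft"`).
#' @examples
#' sch <- ceph_schema()
#' table(sch$tissue)
#' @export
ceph_schema <- function() {
  sch <- data.frame(
    index = 1:60,
    code = c(
      "S", "N", "P", "Ba", "Or", "PNS", "ANS", "A", "SPr", "Spr(p)",
      "UIE", "UIA", "UIR", "UMC", "UMR", "Ptm", "UMA", "LIE", "Id", "Id(l)",
      "LIA", "LIR", "B", "Pg", "Gn", "Me", "Tgo", "Go", "Gop", "Ar",
      "Co", "LMC", "LMR", "Interdental-M", "Interdental-B", "Interdental-I",
      "Cop", "LMA", "Ns", "Prn",
      "Cm", "Sn", "As", "UL", "Stoms", "Stomi", "LL", "Bs", "Pos", "Gns",
      "Mes", "C", "URP-p", "URP", "URA", "URA-a", "LRP-p", "LRP", "LRA",
      "LRA-a"
    ),
    name = c(
      "sella", "nasion", "porion", "basion", "orbitale",
      "posterior nasal spine", "anterior nasal spine", "subspinale",
      "superior prosthion", "palatal superior prosthion",
      "edge of upper incisor", "apex of upper incisor",
      "resistance of upper incisor", "mesial buccal cusp of upper first molar",
      "resistance of upper first molar", "pterygomaxillary fissure",
      "mesial buccal apex of upper first molar", "edge of lower incisor",
      "infradentale", "lingual infradentale", "apex of lower incisor",
      "resistance of lower incisor", "supramental", "pogonion", "gnathion",
      "menton", "tangent gonion", "gonion", "posterior gonion", "articulare",
      "condylion", "mesial cusp of lower first molar",
      "resistance of lower first molar", "midpoint of UMC and LMC",
      "midpoint of upper and lower second bicuspids", "midpoint of UIE and LIE",
      "posterior condylion", "mesial apex of lower first molar",
      "nasion of soft tissue", "pronasale", "columella", "subnasale",
      "subspinale of soft tissue", "upper lip", "stomion superius",
      "stomion inferius", "lower lip", "supramental of soft tissue",
      "pogonion of soft tissue", "gnathion of soft tissue",
      "menton of soft tissue", "cervical point",
      "posterior-resistance-on-bone of upper incisor",
      "posterior-resistance-on-root of upper incisor",
      "anterior-resistance-on-root of upper incisor",
      "anterior-resistance-on-bone of upper incisor",
      "posterior-resistance-on-bone of lower incisor",
      "posterior-resistance-on-root of lower incisor",
      "anterior-resistance-on-root of lower incisor",
      "anterior-resistance-on-bone of lower incisor"
    ),
    tissue = c(rep("hard", 38), rep("soft", 14), rep("hard", 8)),
    stringsAsFactors = FALSE
  )
  class(sch) <- c("ceph_schema", "data.frame")
  sch
}

#' Validate a landmark schema
#'
#' Checks the structural invariants: 60 unique codes with indices 1..60,
#' 46 hard- and 14 soft-tissue entries.
#'
#' @param schema a schema data.frame as returned by [ceph_schema()].
#' @return the schema, invisibly; errors if invalid.
#' @export
validate_schema <- function(schema) {
  if (nrow(schema) != 60L) stop_ceph("schema must have exactly 60 entries", class = "schema_invalid")
  if (!identical(sort(schema$index), 1:60)) stop_ceph("schema indices must be 1..60", class = "schema_invalid")
  if (anyDuplicated(schema$code)) stop_ceph("schema codes must be unique", class = "schema_invalid")
  tt <- table(factor(schema$tissue, levels = c("hard", "soft")))
  if (tt[["hard"]] != 46L || tt[["soft"]] != 14L) {
    stop_ceph("schema must have 46 hard and 14 soft tissue landmarks", class = "schema_invalid")
  }
  invisible(schema)
}
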