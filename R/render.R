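# Deterministic SVG wireframe rendering of templates.

#' Default wireframe connectivity
#'
#' Landmark-code segment list tracing the cranial base, maxillary and
#' mandibular outlines, incisor axes and the soft-tissue profile.
#'
#' @return two-column character matrix of landmark code pairs.
#' @export
default_connectivity <- function() {
  path <- function(codes) cbind(codes[-length(codes)], codes[-1])
  rbind(
    path(c("S", "N")),
    path(c("PNS", "ANS", "A", "SPr")),
    path(c("Co", "Ar", "Go", "Me", "Pg", "B", "Id")),
    path(c("UIA", "UIE")),
    path(c("LIA", "LIE")),
    path(c("Ns", "Prn", "Cm", "Sn", "UL", "Stoms", "Stomi", "LL", "Bs",
           "Pos", "Gns", "Mes"))
  )
}

.svg_header <- function(w, h) {
  c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">', w, h, w, h),
    '<rect width="100%" height="100%" fill="white"/>')
}

.svg_points <- function(xy, colour, r = 1.5) {
  sprintf('<circle cx="%.3f" cy="%.3f" r="%.1f" fill="%s"/>',
          xy[, 1], xy[, 2], r, colour)
}

.svg_segments <- function(xy, connectivity, colour, width = 1) {
  if (is.null(connectivity) || nrow(connectivity) == 0L) return(character(0))
  a <- xy[connectivity[, 1], , drop = FALSE]
  b <- xy[connectivity[, 2], , drop = FALSE]
  sprintf('<line x1="%.3f" y1="%.3f" x2="%.3f" y2="%.3f" stroke="%s" stroke-width="%.1f"/>',
          a[, 1], a[, 2], b[, 1], b[, 2], colour, width)
}

.check_connectivity <- function(connectivity, codes) {
  if (is.null(connectivity)) return(invisible())
  bad <- setdiff(unique(as.vector(connectivity)), codes)
  if (length(bad)) {
    stop_ceph("unknown landmark codes in connectivity: ",
              paste(bad, collapse = ", "), class = "validation_error")
  }
}

.to_px <- function(coords_list, scale = 3, margin = 20) {
  all_xy <- do.call(rbind, coords_list)
  xr <- range(all_xy[, 1])
  yr <- range(all_xy[, 2])
  lapply(coords_list, function(m) {
    cbind(margin + (m[, 1] - xr[1]) * scale,
          margin + (m[, 2] - yr[1]) * scale) # y-down already: drawn as-is
  })
}

#' Render a template as a deterministic SVG wireframe
#'
#' 1 mm maps to a fixed pixel scale, y is drawn downward (the native frame
#' orientation), and the output text is byte-stable for identical input.
#'
#' @param template a `ceph_template` (or a bare `60 x 2` coordinate matrix).
#' @param connectivity two-column matrix of landmark-code pairs (default
#'   [default_connectivity()]; `NULL` or a zero-row matrix draws points
#'   only).
#' @param file optional path; when given the SVG is written there.
#' @param scale pixels per mm.
#' @return the SVG text as a character vector (invisibly when `file` is
#'   given).
#' @export
render_template <- function(template, connectivity = default_connectivity(),
                            file = NULL, scale = 3) {
  m <- if (inherits(template, "ceph_template")) template$mean_coords else template
  .check_connectivity(connectivity, rownames(m))
  px <- .to_px(list(m), scale = scale)[[1]]
  rownames(px) <- rownames(m)
  w <- ceiling(max(px[, 1])) + 20L
  h <- ceiling(max(px[, 2])) + 20L
  svg <- c(.svg_header(w, h),
           .svg_segments(px, connectivity, "black"),
           .svg_points(px, "black"),
           "</svg>")
  if (!is.null(file)) {
    writeLines(svg, file)
    return(invisible(svg))
  }
  svg
}

#' Render a pre/post template overlay with displacement arrows
#'
#' Two wireframe layers (pre in grey, post in black) plus one displacement
#' segment per landmark whose endpoints are the pre and post coordinates
#' (i.e. the drawn arrow equals the post-minus-pre displacement).
#'
#' @param pre,post `ceph_template`s or `60 x 2` coordinate matrices on the
#'   same schema.
#' @param connectivity landmark-code segment list.
#' @param file optional output path.
#' @param scale pixels per mm.
#' @return SVG text (invisibly when `file` is given).
#' @export
render_overlay <- function(pre, post, connectivity = default_connectivity(),
                           file = NULL, scale = 3) {
  m1 <- if (inherits(pre, "ceph_template")) pre$mean_coords else pre
  m2 <- if (inherits(post, "ceph_template")) post$mean_coords else post
  stopifnot(identical(rownames(m1), rownames(m2)))
  .check_connectivity(connectivity, rownames(m1))
  px <- .to_px(list(m1, m2), scale = scale)
  p1 <- px[[1]]; p2 <- px[[2]]
  rownames(p1) <- rownames(m1)
  rownames(p2) <- rownames(m2)
  w <- ceiling(max(p1[, 1], p2[, 1])) + 20L
  h <- ceiling(max(p1[, 2], p2[, 2])) + 20L
  arrows <- sprintf(
    '<line x1="%.3f" y1="%.3f" x2="%.3f" y2="%.3f" stroke="red" stroke-width="0.8" class="displacement"/>',
    p1[, 1], p1[, 2], p2[, 1], p2[, 2])
  svg <- c(.svg_header(w, h),
           .svg_segments(p1, connectivity, "grey"),
           .svg_points(p1, "grey", r = 1.2),
           .svg_segments(p2, connectivity, "black"),
           .svg_points(p2, "black", r = 1.2),
           arrows,
           "</svg>")
  if (!is.null(file)) {
    writeLines(svg, file)
    return(invisible(svg))
  }
  svg
}
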