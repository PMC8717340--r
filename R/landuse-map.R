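#' Land-use map container
#'
#' A `landuse_map` holds categorical land-use polygons in a planar
#' metric CRS. Each polygon carries three hierarchical type codes
#' (`code_l1` coarsest, `code_l3` finest) and a human-readable label,
#' mirroring the three-level national land-use classification the
#' surveillance analysis operates on; all analyses use level-III codes.
#'
#' @param polygons list of polygons, each a list with elements `outer`
#'   (closed ring, n x 2 matrix of meters), `holes` (list of closed rings,
#'   possibly empty), `code_l1`, `code_l2`, `code_l3`, `label`.
#' @param extent numeric `c(xmin, ymin, xmax, ymax)` in meters, or `NULL`
#'   to take the bounding box of the polygons.
#' @return An object of class `landuse_map`.
#' @export
landuse_map <- function(polygons, extent = NULL) {
  stopifnot(is.list(polygons), length(polygons) > 0)
  for (p in polygons) {
    if (is.null(p$outer) || !is.matrix(p$outer) || ncol(p$outer) != 2)
      stop("each polygon needs a closed outer ring as an n x 2 matrix")
    for (f in c("code_l1", "code_l2", "code_l3", "label"))
      if (is.null(p[[f]])) stop("polygon missing field: ", f)
  }
  bboxes <- t(vapply(polygons, function(p) ring_bbox(p$outer), numeric(4)))
  colnames(bboxes) <- c("xmin", "ymin", "xmax", "ymax")
  if (is.null(extent))
    extent <- c(min(bboxes[, "xmin"]), min(bboxes[, "ymin"]),
                max(bboxes[, "xmax"]), max(bboxes[, "ymax"]))
  structure(list(polygons = polygons, bboxes = bboxes,
                 extent = as.numeric(extent)),
            class = "landuse_map")
}

#' @export
print.landuse_map <- function(x, ...) {
  codes <- vapply(x$polygons, `[[`, character(1), "code_l3")
  cat("landuse_map:", length(x$polygons), "polygons,",
      length(unique(codes)), "level-III codes\n")
  cat(sprintf("extent: [%g, %g] x [%g, %g] m\n",
              x$extent[1], x$extent[3], x$extent[2], x$extent[4]))
  invisible(x)
}

#' Land-use code lookup for point locations
#'
#' Finds, for each point, the level-III code of the polygon containing it.
#' A point on a shared boundary of several polygons is assigned to the
#' polygon with the lexicographically smallest level-III code, so the
#' assignment is deterministic. Points in no polygon get `NA`
#' (unclassified), a valid outcome: land-use maps rarely cover a whole
#' study region.
#'
#' @param x,y numeric vectors of point coordinates (meters).
#' @param map a [landuse_map()].
#' @param tol boundary tolerance in meters.
#' @return character vector of level-III codes (`NA` = unclassified).
#' @export
landuse_at <- function(x, y, map, tol = 1e-9) {
  stopifnot(inherits(map, "landuse_map"), length(x) == length(y))
  code <- rep(NA_character_, length(x))
  if (length(x) == 0) return(code)
  bb <- map$bboxes
  for (k in seq_along(map$polygons)) {
    p <- map$polygons[[k]]
    cand <- which(x >= bb[k, "xmin"] - tol & x <= bb[k, "xmax"] + tol &
                    y >= bb[k, "ymin"] - tol & y <= bb[k, "ymax"] + tol)
    if (length(cand) == 0) next
    hit <- points_in_polygon(x[cand], y[cand], p$outer, p$holes, tol)
    if (!any(hit)) next
    idx <- cand[hit]
    take <- is.na(code[idx]) | p$code_l3 < code[idx]
    code[idx[take]] <- p$code_l3
  }
  code
}

# Lookup table from level-III code to the full hierarchy, taken from the
# map's own polygons.
landuse_hierarchy <- function(map) {
  df <- unique(data.frame(
    code_l1 = vapply(map$polygons, `[[`, character(1), "code_l1"),
    code_l2 = vapply(map$polygons, `[[`, character(1), "code_l2"),
    code_l3 = vapply(map$polygons, `[[`, character(1), "code_l3"),
    label = vapply(map$polygons, `[[`, character(1), "label"),
    stringsAsFactors = FALSE))
  df[order(df$code_l3), , drop = FALSE]
}

#' Total map area by level-III code
#'
#' @param map a [landuse_map()].
#' @return data.frame with columns `code_l3`, `label`, `area_m2`.
#' @export
landuse_areas <- function(map) {
  area <- vapply(map$polygons, function(p) {
    abs(ring_area(p$outer)) - sum(vapply(p$holes, function(h)
      abs(ring_area(h)), numeric(1)))
  }, numeric(1))
  code <- vapply(map$polygons, `[[`, character(1), "code_l3")
  label <- vapply(map$polygons, `[[`, character(1), "label")
  agg <- stats::aggregate(area, by = list(code_l3 = code), FUN = sum)
  names(agg)[2] <- "area_m2"
  agg$label <- label[match(agg$code_l3, code)]
  agg[order(agg$code_l3), c("code_l3", "label", "area_m2")]
}
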