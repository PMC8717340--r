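#' Read a tube table
#'
#' Reads the tube CSV dialect (`tube_id, x, y, year, status,
#' grid_spacing_m`; planar meters). Rows with non-finite coordinates, a
#' status outside \{0, 1\}, or a non-positive spacing are rejected; the
#' returned table carries a per-row rejection report in its `rejected`
#' attribute so that accepted + rejected = rows read. Coordinates that
#' look geographic (all within lon/lat bounds with sub-degree spans) are
#' refused outright: every downstream distance is metric, and silent
#' reprojection would hide unit errors.
#'
#' @param path CSV file path.
#' @return validated data.frame of tube records; attribute `rejected` is
#'   a data.frame `row, reason`.
#' @export
read_tubes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("tube_id", "x", "y", "year", "status", "grid_spacing_m")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  df$x <- as.numeric(df$x); df$y <- as.numeric(df$y)
  df$year <- as.integer(df$year)
  df$status <- suppressWarnings(as.integer(df$status))
  df$grid_spacing_m <- as.numeric(df$grid_spacing_m)

  reasons <- rep(NA_character_, nrow(df))
  bad <- !is.finite(df$x) | !is.finite(df$y)
  reasons[bad & is.na(reasons)] <- "non-finite coordinates"
  bad2 <- is.na(df$status) | !(df$status %in% c(0L, 1L))
  reasons[bad2 & is.na(reasons)] <- "status not in {0,1}"
  bad3 <- !is.finite(df$grid_spacing_m) | df$grid_spacing_m <= 0
  reasons[bad3 & is.na(reasons)] <- "non-positive grid spacing"
  bad4 <- is.na(df$year)
  reasons[bad4 & is.na(reasons)] <- "missing year"
  keep <- is.na(reasons)
  rejected <- data.frame(row = which(!keep), reason = reasons[!keep],
                         stringsAsFactors = FALSE)
  out <- df[keep, required, drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) > 1) {
    span <- max(max(out$x) - min(out$x), max(out$y) - min(out$y))
    if (all(abs(out$x) <= 180) && all(abs(out$y) <= 90) && span < 10)
      stop("coordinates look geographic (degrees); supply planar meters")
  }
  attr(out, "rejected") <- rejected
  out
}

#' Write a tube table
#' @param tubes data.frame of tube records.
#' @param path output CSV path.
#' @export
write_tubes <- function(tubes, path) {
  cols <- intersect(c("tube_id", "x", "y", "year", "status",
                      "grid_spacing_m", "weight", "landuse_code"),
                    names(tubes))
  utils::write.csv(tubes[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

ring_to_coords <- function(ring) {
  lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
}

coords_to_ring <- function(coords) {
  m <- matrix(unlist(lapply(coords, function(p) as.numeric(p[1:2]))),
              ncol = 2, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
  # close the ring if needed
  if (any(m[1, ] != m[nrow(m), ])) m <- rbind(m, m[1, ])
  m
}

#' Write a land-use map as GeoJSON
#'
#' Polygon features with `code_l1`, `code_l2`, `code_l3` and `label`
#' properties. The CRS is declared in a top-level `crs_note` member as
#' planar meters (GeoJSON proper mandates WGS84; these are synthetic or
#' projected planar coordinates, which the note makes explicit).
#'
#' @param map a [landuse_map()].
#' @param path output path.
#' @export
write_landuse <- function(map, path) {
  feats <- lapply(map$polygons, function(p) {
    rings <- c(list(ring_to_coords(p$outer)),
               lapply(p$holes, ring_to_coords))
    list(type = "Feature",
         properties = list(code_l1 = p$code_l1, code_l2 = p$code_l2,
                           code_l3 = p$code_l3, label = p$label),
         geometry = list(type = "Polygon", coordinates = rings))
  })
  obj <- list(type = "FeatureCollection",
              crs_note = "planar meters (projected / synthetic)",
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a land-use map from GeoJSON
#'
#' Accepts Polygon and MultiPolygon features carrying the three code
#' properties. Features missing a code property, or with degenerate
#' rings (< 4 points), are rejected and listed in the `rejected`
#' attribute of the result.
#'
#' @param path GeoJSON path.
#' @return a [landuse_map()]; attribute `rejected` lists dropped
#'   features and reasons.
#' @export
read_landuse <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path)
  if (is.null(obj$features)) stop("not a GeoJSON FeatureCollection")
  polys <- list()
  rejected <- data.frame(feature = integer(0), reason = character(0),
                         stringsAsFactors = FALSE)
  for (i in seq_along(obj$features)) {
    f <- obj$features[[i]]
    props <- f$properties
    miss <- setdiff(c("code_l1", "code_l2", "code_l3"), names(props))
    if (length(miss) > 0) {
      rejected <- rbind(rejected, data.frame(
        feature = i, reason = paste("missing property:",
                                    paste(miss, collapse = ", "))))
      next
    }
    geom <- f$geometry
    poly_sets <- switch(geom$type,
                        Polygon = list(geom$coordinates),
                        MultiPolygon = geom$coordinates,
                        NULL)
    if (is.null(poly_sets)) {
      rejected <- rbind(rejected, data.frame(
        feature = i, reason = paste("unsupported geometry:", geom$type)))
      next
    }
    ok <- TRUE
    for (rings in poly_sets) {
      outer <- coords_to_ring(rings[[1]])
      if (nrow(outer) < 4) { ok <- FALSE; break }
      holes <- lapply(rings[-1], coords_to_ring)
      polys[[length(polys) + 1L]] <- list(
        outer = outer, holes = holes,
        code_l1 = as.character(props$code_l1),
        code_l2 = as.character(props$code_l2),
        code_l3 = as.character(props$code_l3),
        label = if (is.null(props$label)) NA_character_
        else as.character(props$label))
    }
    if (!ok)
      rejected <- rbind(rejected, data.frame(
        feature = i, reason = "degenerate ring (< 4 points)"))
  }
  if (length(polys) == 0) stop("no valid polygons in ", path)
  map <- landuse_map(polys)
  attr(map, "rejected") <- rejected
  map
}

#' Write an intensity surface as an ESRI ASCII grid
#'
#' Standard `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value`
#' header followed by rows top-to-bottom.
#'
#' @param surface an `intensity_surface` from [krige_ordinary()].
#' @param path output path.
#' @param what `"pred"` or `"var"`.
#' @export
write_ascii_grid <- function(surface, path, what = c("pred", "var")) {
  what <- match.arg(what)
  m <- surface[[what]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", surface$ncol),
               sprintf("nrows %d", surface$nrow),
               sprintf("xllcorner %.6f", surface$origin[1]),
               sprintf("yllcorner %.6f", surface$origin[2]),
               sprintf("cellsize %.6f", surface$cell_size),
               "NODATA_value -9999"), con)
  for (r in rev(seq_len(surface$nrow)))  # top row first
    writeLines(paste(sprintf("%.6g", m[r, ]), collapse = " "), con)
  invisible(path)
}

#' Write an intensity surface as a gridded CSV
#' @param surface an `intensity_surface`.
#' @param path output CSV path.
#' @export
write_surface_csv <- function(surface, path) {
  g <- expand.grid(col = seq_len(surface$ncol), row = seq_len(surface$nrow))
  df <- data.frame(
    row = g$row, col = g$col,
    x = surface$origin[1] + (g$col - 0.5) * surface$cell_size,
    y = surface$origin[2] + (g$row - 0.5) * surface$cell_size,
    value = surface$pred[cbind(g$row, g$col)],
    variance = surface$var[cbind(g$row, g$col)])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a transition network as an edge-list CSV
#' @param net a `transition_network`.
#' @param path output CSV path.
#' @export
write_edges_csv <- function(net, path) {
  utils::write.csv(net$edges, path, row.names = FALSE)
  invisible(path)
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

#' Write a transition network as GEXF
#'
#' Minimal GEXF 1.2 (directed, weighted) readable by common graph
#' tools.
#'
#' @param net a `transition_network`.
#' @param path output path.
#' @param labels optional named character vector of node labels.
#' @export
write_gexf <- function(net, path, labels = NULL) {
  lab <- function(code) {
    l <- if (!is.null(labels) && code %in% names(labels)) labels[[code]]
    else code
    xml_escape(l)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    '  <graph mode="static" defaultedgetype="directed">',
    "    <nodes>",
    vapply(net$nodes, function(nd) sprintf(
      '      <node id="%s" label="%s" />', xml_escape(nd), lab(nd)),
      character(1)),
    "    </nodes>",
    "    <edges>")
  if (nrow(net$edges) > 0)
    lines <- c(lines, vapply(seq_len(nrow(net$edges)), function(i) sprintf(
      '      <edge id="%d" source="%s" target="%s" weight="%.12g" />',
      i, xml_escape(net$edges$src_code[i]),
      xml_escape(net$edges$dst_code[i]), net$edges$weight[i]),
      character(1)))
  lines <- c(lines, "    </edges>", "  </graph>", "</gexf>")
  writeLines(lines, path)
  invisible(path)
}

#' Write a LISA field as CSV and cell-polygon GeoJSON
#'
#' @param field a [lisa_field()] result.
#' @param csv_path,geojson_path output paths (`NULL` skips either).
#' @export
write_lisa <- function(field, csv_path = NULL, geojson_path = NULL) {
  df <- as.data.frame(field)
  if (!is.null(csv_path))
    utils::write.csv(
      df[, c("cell_id", "row", "col", "x", "y", "I", "pseudo_p", "class")],
      csv_path, row.names = FALSE)
  if (!is.null(geojson_path)) {
    cs <- attr(field, "cell_size")
    org <- attr(field, "origin")
    feats <- lapply(seq_len(nrow(df)), function(i) {
      x0 <- org[1] + (df$col[i] - 1) * cs
      y0 <- org[2] + (df$row[i] - 1) * cs
      ring <- list(c(x0, y0), c(x0 + cs, y0), c(x0 + cs, y0 + cs),
                   c(x0, y0 + cs), c(x0, y0))
      list(type = "Feature",
           properties = list(cell_id = df$cell_id[i], row = df$row[i],
                             col = df$col[i], x = df$x[i], y = df$y[i],
                             I = df$I[i], pseudo_p = df$pseudo_p[i],
                             class = df$class[i]),
           geometry = list(type = "Polygon", coordinates = list(ring)))
    })
    jsonlite::write_json(
      list(type = "FeatureCollection",
           crs_note = "planar meters (projected / synthetic)",
           features = feats),
      geojson_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(field)
}

#' Write a dispersal curve as CSV
#' @param curve a [cumulative_curve()] result.
#' @param path output CSV path.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(
    data.frame(bin_edge_m = curve$bin_m, cumulative_proportion =
                 curve$cum_prop), path, row.names = FALSE)
  invisible(path)
}

#' Load the packaged regional surveillance summary
#'
#' Reads the packaged per-year positive/negative tube counts for the two
#' study regions plus their raw (pre-cleaning) sample totals, and
#' recomputes the derived quantities: per-region totals of positives and
#' of valid samples (as sums of the yearly counts), per-year incidence,
#' and the percentage of raw samples that were valid.
#'
#' @param counts_path,raw_path CSV paths; defaults are the copies
#'   shipped in `inst/extdata`.
#' @return list: `per_year` (region, year, n_positive, n_negative,
#'   n_total, incidence), `totals` (region, n_positive, n_valid_sum —
#'   the sum of the yearly totals —, n_valid — the reported region
#'   total, which in the source differs slightly from the yearly sum —,
#'   n_raw, valid_share_pct = 100 * n_valid / n_raw).
#' @export
load_surveillance_summary <- function(
    counts_path = system.file("extdata", "tube_counts_by_year.csv",
                              package = "antspread"),
    raw_path = system.file("extdata", "raw_sample_totals.csv",
                           package = "antspread")) {
  per_year <- utils::read.csv(counts_path, stringsAsFactors = FALSE)
  stopifnot(all(c("region", "year", "n_positive", "n_negative") %in%
                  names(per_year)))
  per_year$n_total <- per_year$n_positive + per_year$n_negative
  per_year$incidence <- per_year$n_positive / per_year$n_total
  raw <- utils::read.csv(raw_path, stringsAsFactors = FALSE)
  pos <- tapply(per_year$n_positive, per_year$region, sum)
  valid <- tapply(per_year$n_total, per_year$region, sum)
  totals <- data.frame(region = names(pos),
                       n_positive = as.integer(pos),
                       n_valid_sum = as.integer(valid[names(pos)]),
                       stringsAsFactors = FALSE)
  m <- match(totals$region, raw$region)
  totals$n_valid <- as.integer(raw$n_valid_printed[m])
  totals$n_raw <- raw$n_raw[m]
  totals$valid_share_pct <- 100 * totals$n_valid / totals$n_raw
  rownames(totals) <- NULL
  list(per_year = per_year, totals = totals)
}
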