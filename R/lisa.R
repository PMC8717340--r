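#' Aggregate tube weights onto an analysis lattice
#'
#' Builds the cell grid the bivariate LISA runs on: `x` is the summed
#' standardized weight of year-t positives belonging to the designated
#' source land-use type, `y` the summed standardized weight of all
#' year-t+1 positives, per cell. Cells tile the bounding box of the
#' supplied tubes (or an explicit extent).
#'
#' @param labeled_t,labeled_t1 classified, standardized tubes for years
#'   t and t+1 (need `x`, `y`, `status`, `weight`, `landuse_code`).
#' @param source_code level-III land-use code acting as the diffusion
#'   source (e.g. the top-hub type).
#' @param cell_size_m lattice cell size (m), default 500.
#' @param extent optional `c(xmin, ymin, xmax, ymax)`; default is the
#'   bounding box of all supplied tubes.
#' @return data.frame of class `cell_grid` with columns `cell_id, row,
#'   col, cx, cy, x, y` and attributes `nrow`, `ncol`, `cell_size`,
#'   `origin`, `source_code`.
#' @export
aggregate_cells <- function(labeled_t, labeled_t1, source_code,
                            cell_size_m = 500, extent = NULL) {
  if (cell_size_m <= 0) stop("cell_size_m must be > 0")
  all_x <- c(labeled_t$x, labeled_t1$x)
  all_y <- c(labeled_t$y, labeled_t1$y)
  if (length(all_x) == 0) stop("no tubes to aggregate")
  if (is.null(extent))
    extent <- c(min(all_x), min(all_y), max(all_x), max(all_y))
  origin <- extent[1:2]
  nc <- max(1L, ceiling((extent[3] - origin[1]) / cell_size_m - 1e-9))
  nr <- max(1L, ceiling((extent[4] - origin[2]) / cell_size_m - 1e-9))

  cell_of <- function(px, py) {
    col <- pmin(nc, pmax(1L, ceiling((px - origin[1]) / cell_size_m - 1e-9)))
    row <- pmin(nr, pmax(1L, ceiling((py - origin[2]) / cell_size_m - 1e-9)))
    (row - 1L) * nc + col
  }
  grid <- expand.grid(col = seq_len(nc), row = seq_len(nr))
  out <- data.frame(cell_id = (grid$row - 1L) * nc + grid$col,
                    row = grid$row, col = grid$col,
                    cx = origin[1] + (grid$col - 0.5) * cell_size_m,
                    cy = origin[2] + (grid$row - 0.5) * cell_size_m,
                    x = 0, y = 0)
  out <- out[order(out$cell_id), , drop = FALSE]
  rownames(out) <- NULL

  src <- labeled_t[labeled_t$status == 1L &
                     !is.na(labeled_t$landuse_code) &
                     labeled_t$landuse_code == source_code, , drop = FALSE]
  if (nrow(src) > 0) {
    agg <- tapply(src$weight, cell_of(src$x, src$y), sum)
    out$x[match(as.integer(names(agg)), out$cell_id)] <- as.numeric(agg)
  }
  tgt <- labeled_t1[labeled_t1$status == 1L, , drop = FALSE]
  if (nrow(tgt) > 0) {
    agg <- tapply(tgt$weight, cell_of(tgt$x, tgt$y), sum)
    out$y[match(as.integer(names(agg)), out$cell_id)] <- as.numeric(agg)
  }
  structure(out, nrow = nr, ncol = nc, cell_size = cell_size_m,
            origin = origin, source_code = source_code,
            class = c("cell_grid", "data.frame"))
}

#' Spatial weights on the cell lattice
#'
#' Queen (edge- or corner-adjacent) or rook (edge-adjacent) contiguity
#' neighbors on the rectangular cell lattice, optionally row-
#' standardized so each non-isolated cell's weights sum to 1. Cells with
#' no neighbors are flagged isolated.
#'
#' @param grid an [aggregate_cells()] result (or any data.frame with
#'   `row`, `col` on a full lattice).
#' @param scheme `"queen"` (default) or `"rook"`.
#' @param row_standardize logical, default `TRUE`.
#' @return list of class `spatial_weights`: `neighbors` (list of integer
#'   indices into the grid rows), `weights` (matching numeric lists),
#'   `scheme`, `row_standardized`, `isolated` (logical per cell).
#' @export
build_weights <- function(grid, scheme = c("queen", "rook"),
                          row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  n <- nrow(grid)
  if (n == 0) stop("empty grid")
  offsets <- if (scheme == "queen")
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
          dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  else
    cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  idx <- new.env(parent = emptyenv())
  key <- function(r, c) paste(r, c, sep = ",")
  for (i in seq_len(n)) assign(key(grid$row[i], grid$col[i]), i, envir = idx)
  neighbors <- vector("list", n)
  weights <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- integer(0)
    for (k in seq_len(nrow(offsets))) {
      kk <- key(grid$row[i] + offsets[k, "dr"],
                grid$col[i] + offsets[k, "dc"])
      j <- idx[[kk]]
      if (!is.null(j)) nb <- c(nb, j)
    }
    nb <- sort(nb)
    neighbors[[i]] <- nb
    weights[[i]] <- if (length(nb) == 0) numeric(0)
    else if (row_standardize) rep(1 / length(nb), length(nb))
    else rep(1, length(nb))
  }
  structure(list(neighbors = neighbors, weights = weights,
                 scheme = scheme, row_standardized = row_standardize,
                 isolated = lengths(neighbors) == 0),
            class = "spatial_weights")
}

# Spatial lag: (W z)_i = sum_j w_ij z_j. NA for isolated cells.
spatial_lag <- function(W, z) {
  vapply(seq_along(W$neighbors), function(i) {
    if (length(W$neighbors[[i]]) == 0) return(NA_real_)
    sum(W$weights[[i]] * z[W$neighbors[[i]]])
  }, numeric(1))
}

# Population z-scores (divide by sqrt of the population variance).
# A constant vector is degenerate: its z-scores (and hence the local
# Moran statistic) are identically zero.
zscore_pop <- function(v, what, on_degenerate = c("warn", "error")) {
  on_degenerate <- match.arg(on_degenerate)
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s <= 0) {
    msg <- paste0("degenerate input: zero variance in ", what)
    if (on_degenerate == "error") stop(msg)
    warning(msg, "; statistic is identically zero")
    return(list(z = rep(0, length(v)), mean = m, sd = 0))
  }
  list(z = (v - m) / s, mean = m, sd = s)
}

#' Bivariate local Moran's I
#'
#' I_i = z_x(i) * sum_j w_ij z_y(j): the association between the source
#' intensity at cell i in year t and the overall intensity in its
#' neighborhood in year t+1. Both variables are z-scored with population
#' means and standard deviations over all non-isolated cells. Positive
#' values flag persistently intense neighborhoods (hot spots), negative
#' values flag cells whose neighborhood lights up next year relative to
#' the cell's own source intensity (diffusion areas).
#'
#' @param x,y numeric vectors over the grid cells (source-type year-t
#'   and overall year-t+1 intensities).
#' @param W a [build_weights()] result.
#' @param on_degenerate with zero variance in `x` or `y` the statistic
#'   is identically zero; `"warn"` (default) returns it as such with a
#'   warning naming the offending variable, `"error"` stops instead.
#' @return list: `I` (per cell, `NA` for isolated cells), `moments`
#'   (list `mean_x, mean_y, sd_x, sd_y`), `isolated`.
#' @export
bivariate_local_moran <- function(x, y, W,
                                  on_degenerate = c("warn", "error")) {
  n <- length(x)
  if (length(y) != n || length(W$neighbors) != n)
    stop("x, y and W must have matching lengths")
  use <- !W$isolated
  if (sum(use) < 2) stop("fewer than 2 non-isolated cells")
  zx <- rep(NA_real_, n); zy <- rep(NA_real_, n)
  sx <- zscore_pop(x[use], "x", on_degenerate)
  sy <- zscore_pop(y[use], "y", on_degenerate)
  zx[use] <- sx$z; zy[use] <- sy$z
  lag <- spatial_lag(W, ifelse(is.na(zy), 0, zy))
  I <- zx * lag
  I[!use] <- NA_real_
  list(I = I,
       moments = list(mean_x = sx$mean, mean_y = sy$mean,
                      sd_x = sx$sd, sd_y = sy$sd),
       isolated = W$isolated)
}

#' Conditional-permutation pseudo p-values for bivariate local Moran
#'
#' For each cell i, the observed I_i is compared against `n_perm`
#' replicates in which cell i's own z_x is held fixed and its neighbors'
#' z_y values are drawn without replacement from the y z-scores of all
#' other cells. Two-sided: pseudo_p = (1 + #\{|I_perm| >= |I_obs|\}) /
#' (n_perm + 1). Seeded and reproducible.
#'
#' @inheritParams bivariate_local_moran
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return numeric pseudo p-values per cell (`NA` for isolated cells).
#' @export
permutation_pvalues <- function(x, y, W, n_perm = 999, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- bivariate_local_moran(x, y, W)
  n <- length(x)
  use <- which(!W$isolated)
  zy <- rep(NA_real_, n)
  sy <- zscore_pop(y[use], "y")
  zy[use] <- sy$z
  sx <- zscore_pop(x[use], "x")
  zx <- rep(NA_real_, n); zx[use] <- sx$z
  set.seed(seed)
  p <- rep(NA_real_, n)
  for (i in use) {
    nb <- W$neighbors[[i]]
    k <- length(nb)
    wts <- W$weights[[i]]
    pool <- zy[setdiff(use, i)]
    if (length(pool) < k) { p[i] <- NA_real_; next }
    draws <- matrix(0, n_perm, k)
    for (r in seq_len(n_perm))
      draws[r, ] <- pool[sample.int(length(pool), k)]
    I_perm <- zx[i] * as.vector(draws %*% wts)
    p[i] <- (1 + sum(abs(I_perm) >= abs(obs$I[i]))) / (n_perm + 1)
  }
  p
}

#' Classify cells into hot spots and diffusion areas
#'
#' Significant positive I -> `"hotspot"` (sustained high intensity
#' across the year pair); significant negative I -> `"diffusion"`
#' (the neighborhood intensifies in the later year); otherwise
#' `"nonsignificant"`; cells without neighbors -> `"isolated"`.
#'
#' @param I local Moran values ([bivariate_local_moran()]).
#' @param p pseudo p-values ([permutation_pvalues()]).
#' @param alpha significance level in (0, 1).
#' @param isolated optional logical vector of isolated cells (default:
#'   cells with `NA` statistics).
#' @return character vector of classes.
#' @export
classify_cells <- function(I, p, alpha = 0.05, isolated = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (length(I) != length(p)) stop("I and p must have matching lengths")
  if (is.null(isolated)) isolated <- is.na(I)
  cls <- rep("nonsignificant", length(I))
  cls[isolated] <- "isolated"
  sig <- !isolated & !is.na(p) & p < alpha
  cls[sig & I > 0] <- "hotspot"
  cls[sig & I < 0] <- "diffusion"
  cls
}

#' Bivariate LISA field for one year pair
#'
#' Composition: aggregate to cells, build weights, compute local Moran,
#' permutation p-values and the hotspot/diffusion classification.
#'
#' @inheritParams aggregate_cells
#' @inheritParams build_weights
#' @inheritParams permutation_pvalues
#' @param alpha significance level.
#' @return the cell grid with `I`, `pseudo_p` and `class` columns
#'   appended (class `lisa_field`).
#' @export
lisa_field <- function(labeled_t, labeled_t1, source_code,
                       cell_size_m = 500, extent = NULL,
                       scheme = "queen", n_perm = 999, alpha = 0.05,
                       seed = 1L) {
  grid <- aggregate_cells(labeled_t, labeled_t1, source_code,
                          cell_size_m, extent)
  W <- build_weights(grid, scheme)
  lm <- bivariate_local_moran(grid$x, grid$y, W)
  p <- permutation_pvalues(grid$x, grid$y, W, n_perm, seed)
  grid$I <- lm$I
  grid$pseudo_p <- p
  grid$class <- classify_cells(lm$I, p, alpha, isolated = W$isolated)
  class(grid) <- c("lisa_field", class(grid))
  grid
}
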