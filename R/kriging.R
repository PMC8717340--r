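#' Empirical semivariogram (Matheron estimator)
#'
#' Bins all point pairs by separation distance and computes the classical
#' Matheron semivariance per bin, gamma(h) = sum (z_i - z_j)^2 / (2 N(h)).
#'
#' @param coords n x 2 matrix (or data.frame with `x`, `y`) of planar
#'   meters.
#' @param values numeric vector of length n.
#' @param n_lags number of equal-width lag bins.
#' @param max_lag_m upper distance cutoff (m); defaults to half the
#'   maximum pairwise distance.
#' @return data.frame of class `empirical_variogram` with columns
#'   `lag_m` (bin centers), `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(coords, values, n_lags = 12,
                                max_lag_m = NULL) {
  coords <- as_coord_matrix(coords)
  n <- nrow(coords)
  if (n < 2) stop("need at least 2 points")
  if (length(values) != n) stop("values must match coords")
  d <- as.vector(stats::dist(coords))
  if (all(d < 1e-12)) stop("all points coincident")
  if (is.null(max_lag_m)) max_lag_m <- max(d) / 2
  if (max_lag_m <= 0) stop("max_lag_m must be > 0")
  dz2 <- as.vector(stats::dist(matrix(values, ncol = 1)))^2
  keep <- d <= max_lag_m & d > 0
  width <- max_lag_m / n_lags
  bin <- pmin(n_lags, ceiling(d[keep] / width))
  gamma <- rep(NA_real_, n_lags)
  npairs <- integer(n_lags)
  if (any(keep)) {
    sums <- tapply(dz2[keep], bin, sum)
    cnts <- tapply(dz2[keep], bin, length)
    ix <- as.integer(names(sums))
    gamma[ix] <- sums / (2 * cnts)
    npairs[ix] <- as.integer(cnts)
  }
  out <- data.frame(lag_m = width * (seq_len(n_lags) - 0.5),
                    gamma = gamma, n_pairs = npairs)
  class(out) <- c("empirical_variogram", "data.frame")
  out
}

#' Evaluate a variogram model
#'
#' gamma(0) = 0 by convention; for h > 0 the nugget applies in full.
#'
#' @param model a [fit_variogram()] result or a list with `family`,
#'   `nugget`, `psill`, `range_m`.
#' @param h distances (m).
#' @return semivariance values gamma(h).
#' @export
variogram_value <- function(model, h) {
  g0 <- switch(model$family,
    spherical = ifelse(h >= model$range_m, 1,
                       1.5 * h / model$range_m - 0.5 * (h / model$range_m)^3),
    exponential = 1 - exp(-3 * h / model$range_m),
    gaussian = 1 - exp(-3 * (h / model$range_m)^2),
    stop("unknown variogram family: ", model$family))
  ifelse(h <= 0, 0, model$nugget + model$psill * g0)
}

#' Fit a variogram model by weighted least squares
#'
#' Fits nugget, partial sill and range of the chosen family to an
#' empirical variogram, minimizing sum N(h) / h^2 * (gamma_hat - gamma)^2
#' (pair-count over squared-lag weights, emphasizing short lags, where
#' kriging weights are most sensitive).
#'
#' @param emp an [empirical_variogram()].
#' @param family one of `"spherical"`, `"exponential"`, `"gaussian"`.
#' @return list of class `variogram_model`: `family`, `nugget`, `psill`,
#'   `range_m`, `converged`, `pure_nugget` (TRUE with a warning when the
#'   empirical variogram is flat at zero).
#' @export
fit_variogram <- function(emp, family = c("spherical", "exponential",
                                          "gaussian")) {
  family <- match.arg(family)
  occ <- !is.na(emp$gamma) & emp$n_pairs > 0
  if (sum(occ) < 3) stop("need >= 3 occupied lag bins")
  h <- emp$lag_m[occ]; g <- emp$gamma[occ]; np <- emp$n_pairs[occ]
  if (max(g) < 1e-15) {
    warning("flat zero variogram; returning pure-nugget model")
    return(structure(list(family = family, nugget = 0, psill = 0,
                          range_m = max(h), converged = TRUE,
                          pure_nugget = TRUE),
                     class = "variogram_model"))
  }
  wts <- np / h^2
  obj <- function(par) {
    m <- list(family = family, nugget = par[1], psill = par[2],
              range_m = par[3])
    sum(wts * (variogram_value(m, h) - g)^2)
  }
  sill0 <- max(g)
  start <- c(nugget = max(1e-6 * sill0, min(g) * 0.5), psill = sill0,
             range_m = max(h) / 2)
  fit <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = c(0, 0, max(h) * 1e-3),
                      upper = c(sill0 * 2, sill0 * 4, max(h) * 10))
  structure(list(family = family, nugget = unname(fit$par[1]),
                 psill = unname(fit$par[2]), range_m = unname(fit$par[3]),
                 converged = fit$convergence == 0, pure_nugget = FALSE),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram_model: %s(nugget = %.4g, psill = %.4g, range = %.4g m)%s\n",
              x$family, x$nugget, x$psill, x$range_m,
              if (isTRUE(x$pure_nugget)) " [pure nugget]" else ""))
  invisible(x)
}

as_coord_matrix <- function(coords) {
  if (is.data.frame(coords)) {
    stopifnot(all(c("x", "y") %in% names(coords)))
    coords <- cbind(coords$x, coords$y)
  }
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  stopifnot(ncol(coords) == 2)
  coords
}

# Average values at exactly duplicated coordinates so the kriging system
# is non-singular.
dedupe_points <- function(coords, values) {
  key <- paste(sprintf("%.9f", coords[, 1]), sprintf("%.9f", coords[, 2]))
  if (!anyDuplicated(key)) return(list(coords = coords, values = values))
  agg <- tapply(values, key, mean)
  first <- !duplicated(key)
  ord <- key[first]
  list(coords = coords[first, , drop = FALSE], values = as.numeric(agg[ord]))
}

#' Ordinary kriging
#'
#' Solves the ordinary-kriging system in covariance form (with a Lagrange
#' multiplier enforcing that prediction weights sum to one) at each
#' target location. With more than `neighborhood_limit` data points, each
#' target uses only its `k_nearest` nearest data points; below the limit
#' the full (global) system is solved.
#'
#' @param coords data coordinates (n x 2 matrix or data.frame `x`, `y`).
#' @param values observed values (here: standardized positive-tube
#'   weights, negatives contributing zeros).
#' @param model a [fit_variogram()] model (or compatible list).
#' @param targets target coordinates (m x 2), or `NULL` to use `grid`.
#' @param grid list `origin = c(x, y), cell_size, nrow, ncol` describing
#'   a prediction lattice of cell centers.
#' @param k_nearest neighborhood size used above `neighborhood_limit`.
#' @param neighborhood_limit data size above which the local
#'   neighborhood is used (default 2000).
#' @return If `grid` given: an `intensity_surface` (list with the grid
#'   spec plus `pred` and `var` matrices, row 1 = bottom row of cells).
#'   Else a data.frame `x, y, pred, var`.
#' @export
krige_ordinary <- function(coords, values, model, targets = NULL,
                           grid = NULL, k_nearest = 16,
                           neighborhood_limit = 2000) {
  coords <- as_coord_matrix(coords)
  if (length(values) != nrow(coords)) stop("values must match coords")
  dd <- dedupe_points(coords, values)
  coords <- dd$coords; values <- dd$values
  n <- nrow(coords)
  if (n < 2) stop("need >= 2 distinct data points")
  as_grid <- !is.null(grid)
  if (as_grid) {
    cx <- grid$origin[1] + grid$cell_size * (seq_len(grid$ncol) - 0.5)
    cy <- grid$origin[2] + grid$cell_size * (seq_len(grid$nrow) - 0.5)
    targets <- as.matrix(expand.grid(x = cx, y = cy))
  } else {
    targets <- as_coord_matrix(targets)
  }
  sill <- model$nugget + model$psill
  cov_of <- function(h) sill - variogram_value(model, h)

  predict_block <- function(didx, tpts) {
    m <- length(didx)
    D <- as.matrix(stats::dist(coords[didx, , drop = FALSE]))
    A <- rbind(cbind(cov_of(D), 1), c(rep(1, m), 0))
    diag(A)[seq_len(m)] <- sill  # C(0) includes the nugget
    Ainv <- solve(A)
    dx <- outer(tpts[, 1], coords[didx, 1], "-")
    dy <- outer(tpts[, 2], coords[didx, 2], "-")
    h0 <- sqrt(dx * dx + dy * dy)
    c0 <- cov_of(h0)
    # exact interpolation: covariance to a coincident datum is C(0) = sill
    c0[h0 < 1e-12] <- sill
    B <- cbind(c0, 1)
    lam <- B %*% Ainv  # rows: weights (m) + Lagrange multiplier
    pred <- as.vector(lam[, seq_len(m), drop = FALSE] %*% values[didx])
    varg <- sill - rowSums(lam * B)
    list(pred = pred, var = pmax(varg, 0), lambda_sum =
           rowSums(lam[, seq_len(m), drop = FALSE]))
  }

  nt <- nrow(targets)
  pred <- numeric(nt); varg <- numeric(nt); lsum <- numeric(nt)
  if (n <= neighborhood_limit) {
    res <- predict_block(seq_len(n), targets)
    pred <- res$pred; varg <- res$var; lsum <- res$lambda_sum
  } else {
    k <- min(k_nearest, n)
    for (i in seq_len(nt)) {
      d2 <- (coords[, 1] - targets[i, 1])^2 + (coords[, 2] - targets[i, 2])^2
      didx <- order(d2)[seq_len(k)]
      res <- predict_block(didx, targets[i, , drop = FALSE])
      pred[i] <- res$pred; varg[i] <- res$var; lsum[i] <- res$lambda_sum
    }
  }
  if (max(abs(lsum - 1)) > 1e-8)
    warning("kriging weight sums deviate from 1 beyond tolerance")
  if (as_grid) {
    structure(list(origin = grid$origin, cell_size = grid$cell_size,
                   nrow = grid$nrow, ncol = grid$ncol,
                   pred = matrix(pred, nrow = grid$nrow, ncol = grid$ncol,
                                 byrow = TRUE),
                   var = matrix(varg, nrow = grid$nrow, ncol = grid$ncol,
                                byrow = TRUE),
                   lambda_sum = lsum),
              class = "intensity_surface")
  } else {
    data.frame(x = targets[, 1], y = targets[, 2], pred = pred, var = varg,
               lambda_sum = lsum)
  }
}

#' @export
print.intensity_surface <- function(x, ...) {
  cat(sprintf("intensity_surface: %d x %d cells of %g m, origin (%g, %g)\n",
              x$nrow, x$ncol, x$cell_size, x$origin[1], x$origin[2]))
  cat(sprintf("predicted range: [%.4g, %.4g]\n",
              min(x$pred), max(x$pred)))
  invisible(x)
}

#' Kriged intensity surface of standardized positives
#'
#' End-to-end helper for one survey year: fits a variogram to the
#' standardized tube weights (negative tubes contribute value-0 points
#' by default, which keeps the surface honest about where surveillance
#' found nothing) and krigs them onto a regular grid covering the tubes.
#'
#' @param wtubes standardized tubes ([standardize_tubes()]) for one year.
#' @param cell_size_m prediction cell size (m).
#' @param family variogram family.
#' @param include_negatives if `FALSE`, only positive tubes enter.
#' @param n_lags,max_lag_m passed to [empirical_variogram()].
#' @return an `intensity_surface` with the fitted `model` attached.
#' @export
krige_intensity <- function(wtubes, cell_size_m = 250,
                            family = "spherical",
                            include_negatives = TRUE,
                            n_lags = 12, max_lag_m = NULL) {
  stopifnot(all(c("x", "y", "weight") %in% names(wtubes)))
  if (!include_negatives) wtubes <- wtubes[wtubes$weight > 0, , drop = FALSE]
  coords <- cbind(wtubes$x, wtubes$y)
  emp <- empirical_variogram(coords, wtubes$weight, n_lags, max_lag_m)
  model <- fit_variogram(emp, family)
  origin <- c(min(wtubes$x), min(wtubes$y))
  nc <- max(1L, ceiling((max(wtubes$x) - origin[1]) / cell_size_m))
  nr <- max(1L, ceiling((max(wtubes$y) - origin[2]) / cell_size_m))
  surf <- krige_ordinary(coords, wtubes$weight, model,
                         grid = list(origin = origin, cell_size = cell_size_m,
                                     nrow = nr, ncol = nc))
  surf$model <- model
  surf
}
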