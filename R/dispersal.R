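#' Nearest-source distances between consecutive survey years
#'
#' For each positive tube of year t+1, the minimum Euclidean distance to
#' any positive tube of year t. This is the sample the cumulative
#' dispersal curve is built from: drawing a circle of radius d around
#' each year-t positive covers the fraction of year-t+1 positives whose
#' nearest source lies within d.
#'
#' @param positives_t data.frame of year-t positive tubes (`x`, `y`).
#' @param positives_t1 data.frame of year-t+1 positive tubes (`x`, `y`,
#'   optionally `tube_id` and `weight`).
#' @return data.frame `tube_id, d_min, w` (one row per year-t+1
#'   positive; `w` = 1 when no weight column is present).
#' @export
nearest_source_distances <- function(positives_t, positives_t1) {
  if (is.null(positives_t) || nrow(positives_t) == 0)
    stop("no source year: year-t positives are empty")
  if (is.null(positives_t1) || nrow(positives_t1) == 0)
    stop("year-t+1 positives are empty")
  d <- min_dist_to_set(positives_t1$x, positives_t1$y,
                       positives_t$x, positives_t$y)
  data.frame(
    tube_id = if ("tube_id" %in% names(positives_t1))
      positives_t1$tube_id else as.character(seq_len(nrow(positives_t1))),
    d_min = d,
    w = if ("weight" %in% names(positives_t1))
      positives_t1$weight else rep(1, nrow(positives_t1)),
    stringsAsFactors = FALSE)
}

#' Cumulative dispersal-proportion curve
#'
#' Bins nearest-source distances into uniform-width bins and returns the
#' cumulative proportion at each bin's upper edge. By default samples
#' are weighted by their standardized tube weights; `weighted = FALSE`
#' uses raw counts.
#'
#' @param samples data.frame from [nearest_source_distances()] (columns
#'   `d_min`, `w`).
#' @param bin_width_m bin width (m), default 50.
#' @param weighted use standardized weights (default) or raw counts.
#' @return data.frame of class `dispersal_curve` with columns `bin_m`
#'   (upper edges) and `cum_prop`; the last value is exactly 1.
#' @export
cumulative_curve <- function(samples, bin_width_m = 50, weighted = TRUE) {
  if (nrow(samples) == 0) stop("no distance samples")
  if (bin_width_m <= 0) stop("bin width must be > 0")
  w <- if (weighted) samples$w else rep(1, nrow(samples))
  if (any(w <= 0)) stop("sample weights must be > 0")
  k_max <- max(1L, ceiling(max(samples$d_min) / bin_width_m - 1e-12))
  edges <- bin_width_m * seq_len(k_max)
  cum <- vapply(edges, function(b) sum(w[samples$d_min <= b]), numeric(1))
  out <- data.frame(bin_m = edges, cum_prop = cum / sum(w))
  class(out) <- c("dispersal_curve", "data.frame")
  out
}

#' Turning point of a cumulative curve (extreme-distance estimator)
#'
#' Locates the critical distance on a cumulative proportion diagram via
#' chord residuals. Let L be the chord joining the first and last curve
#' points and s_k = p_k - L(b_k) the signed vertical residuals. For a
#' sigmoid-shaped curve (residuals of both signs) the turning point is
#' the midpoint of the extreme-residual abscissas,
#' (b_argmax(s) + b_argmin(s)) / 2; for a purely convex or concave curve
#' (one-signed residuals) it is the knee b_argmax(|s|). The result is at
#' the curve's bin resolution.
#'
#' @param curve a [cumulative_curve()] result, or any data.frame with
#'   the curve's abscissas and ordinates in its first two columns.
#' @param tol residual tolerance below which the curve is declared
#'   indistinguishable from its chord.
#' @return the turning-point abscissa `d_star` (m).
#' @export
ede_turning_point <- function(curve, tol = 1e-9) {
  b <- curve[[1]]; p <- curve[[2]]
  if (length(b) < 3) stop("need >= 3 curve points")
  n <- length(b)
  chord <- p[1] + (p[n] - p[1]) * (b - b[1]) / (b[n] - b[1])
  s <- p - chord
  if (max(abs(s)) <= tol)
    stop("degenerate curve: indistinguishable from its chord")
  if (max(s) > tol && min(s) < -tol) {
    (b[which.max(s)] + b[which.min(s)]) / 2
  } else {
    b[which.max(abs(s))]
  }
}

#' Critical dispersal distance for one year pair
#'
#' Composition: nearest-source distances, cumulative curve, turning
#' point.
#'
#' @inheritParams nearest_source_distances
#' @inheritParams cumulative_curve
#' @return list of class `critical_distance`: `d_star` (m), `curve`,
#'   `n_samples`, `max_distance_m` (the distance at which the cumulative
#'   proportion reaches 100%).
#' @export
critical_distance <- function(positives_t, positives_t1, bin_width_m = 50,
                              weighted = TRUE) {
  samples <- nearest_source_distances(positives_t, positives_t1)
  curve <- cumulative_curve(samples, bin_width_m, weighted)
  structure(list(d_star = ede_turning_point(curve), curve = curve,
                 n_samples = nrow(samples),
                 max_distance_m = max(samples$d_min)),
            class = "critical_distance")
}

#' @export
print.critical_distance <- function(x, ...) {
  cat(sprintf("critical_distance: d* = %g m (%d samples, max %g m)\n",
              x$d_star, x$n_samples, x$max_distance_m))
  invisible(x)
}

#' Average critical dispersal distance across year pairs
#'
#' The arithmetic mean of per-year-pair turning points, the quantity
#' adopted as the region-level critical dispersal distance (e.g. 600 m
#' from yearly values 500, 550 and 750 m).
#'
#' @param values numeric vector of yearly critical distances (m).
#' @return their arithmetic mean (m).
#' @export
mean_critical_distance <- function(values) {
  if (length(values) == 0) stop("empty list of critical distances")
  if (any(!is.finite(values))) stop("critical distances must be finite")
  mean(values)
}
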