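#' Density-standardization weight for a positive tube
#'
#' Surveys run at different trap densities are not directly comparable: a
#' tube on a dense lattice is more likely to intercept a colony than one
#' on a sparse lattice. Each positive tube is therefore weighted by the
#' area of lattice cell it represents relative to the reference density,
#' `(spacing_m / reference_m)^2`. At the 200-m reference a positive tube
#' counts as 1; on a 100-m lattice as (100/200)^2 = 0.25; on a 600-m
#' lattice as (600/200)^2 = 9.
#'
#' @param spacing_m lattice spacing of the tube's sampling stratum (m).
#' @param reference_m reference lattice spacing (m), default 200.
#' @return numeric weight(s), `(spacing_m / reference_m)^2`.
#' @export
#' @examples
#' standard_weight(100)  # 0.25
#' standard_weight(600)  # 9
standard_weight <- function(spacing_m, reference_m = 200) {
  if (any(!is.finite(spacing_m)) || any(spacing_m <= 0))
    stop("spacing_m must be positive and finite")
  if (any(!is.finite(reference_m)) || any(reference_m <= 0))
    stop("reference_m must be positive and finite")
  (spacing_m / reference_m)^2
}

#' Standardize a tube table across sampling densities
#'
#' Adds a `weight` column: positive tubes get [standard_weight()] of
#' their stratum spacing, negative tubes get 0 (a negative tube carries
#' no standardized positives). No other field is altered and the record
#' count is preserved.
#'
#' @param tubes data.frame with at least `status` (1 = positive,
#'   0 = negative) and `grid_spacing_m` columns.
#' @param reference_m reference lattice spacing (m).
#' @return the input data.frame with a `weight` column appended.
#' @export
standardize_tubes <- function(tubes, reference_m = 200) {
  stopifnot(is.data.frame(tubes),
            all(c("status", "grid_spacing_m") %in% names(tubes)))
  if (!all(tubes$status %in% c(0L, 1L)))
    stop("status must be binary 0/1")
  w <- standard_weight(tubes$grid_spacing_m, reference_m)
  tubes$weight <- ifelse(tubes$status == 1L, w, 0)
  tubes
}

#' Incidence rates by group
#'
#' Incidence is the number of positive tubes divided by the number of all
#' tubes in the group — raw counts, deliberately not density-standardized
#' weights, since both numerator and denominator come from the same
#' lattice. Groups are typically survey years or land-use codes (at any
#' hierarchy level); tubes with a missing group label are excluded.
#'
#' @param tubes data.frame with a binary `status` column.
#' @param by either the name of a column of `tubes` or a vector of group
#'   labels of length `nrow(tubes)`.
#' @return data.frame `group, n_positive, n_total, incidence`, one row
#'   per non-empty group.
#' @export
incidence_table <- function(tubes, by) {
  stopifnot(is.data.frame(tubes), "status" %in% names(tubes))
  g <- if (length(by) == 1 && is.character(by) && by %in% names(tubes))
    tubes[[by]] else by
  if (length(g) != nrow(tubes))
    stop("group labels must match the number of tubes")
  keep <- !is.na(g)
  g <- as.character(g[keep])
  s <- tubes$status[keep]
  if (!all(s %in% c(0L, 1L))) stop("status must be binary 0/1")
  pos <- tapply(s, g, sum)
  tot <- tapply(s, g, length)
  out <- data.frame(group = names(tot),
                    n_positive = as.integer(pos[names(tot)]),
                    n_total = as.integer(tot),
                    stringsAsFactors = FALSE)
  out$incidence <- out$n_positive / out$n_total
  rownames(out) <- NULL
  out[order(out$group), , drop = FALSE]
}
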