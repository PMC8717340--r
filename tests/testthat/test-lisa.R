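lattice_grid <- function(nr, nc, cell = 500) {
  g <- expand.grid(col = seq_len(nc), row = seq_len(nr))
  data.frame(cell_id = (g$row - 1L) * nc + g$col, row = g$row, col = g$col,
             cx = (g$col - 0.5) * cell, cy = (g$row - 0.5) * cell)
}

test_that("cell aggregation sums weights by cell and source type", {
  t1 <- data.frame(x = c(100, 150, 900, 2600), y = c(100, 120, 80, 100),
                   status = 1L, weight = c(0.25, 1, 9, 1),
                   landuse_code = c("S", "S", "O", "S"))
  t2 <- data.frame(x = c(120, 1300), y = c(110, 90), status = 1L,
                   weight = c(1, 0.25), landuse_code = c("O", "S"))
  grid <- aggregate_cells(t1, t2, source_code = "S", cell_size_m = 500)
  # x: only source-type year-t positives; (100,100) and (150,120) share a cell
  cell1 <- grid[grid$row == 1 & grid$col == 1, ]
  expect_equal(cell1$x, 1.25)
  expect_equal(cell1$y, 1)       # all year-t+1 positives, any type
  cell2 <- grid[grid$row == 1 & grid$col == 2, ]
  expect_equal(cell2$x, 0)       # "O"-type source ignored
  # direct group-by oracle over every cell
  cs <- attr(grid, "cell_size")
  org <- attr(grid, "origin")
  clamp <- function(v, hi) pmin(hi, pmax(1, ceiling(v / cs - 1e-9)))
  col_of <- clamp(t1$x - org[1], attr(grid, "ncol"))
  row_of <- clamp(t1$y - org[2], attr(grid, "nrow"))
  for (i in seq_len(nrow(grid))) {
    inx <- t1$landuse_code == "S" & col_of == grid$col[i] &
      row_of == grid$row[i]
    expect_equal(grid$x[i], sum(t1$weight[inx]))
  }

  # no source-type positives anywhere: all x zero
  g0 <- aggregate_cells(t1, t2, source_code = "Z", cell_size_m = 500)
  expect_true(all(g0$x == 0))
})

test_that("queen weights have the textbook neighbor counts and symmetry", {
  grid <- lattice_grid(3, 3)
  W <- build_weights(grid, "queen")
  center <- which(grid$row == 2 & grid$col == 2)
  corner <- which(grid$row == 1 & grid$col == 1)
  expect_equal(length(W$neighbors[[center]]), 8)
  expect_equal(W$weights[[center]], rep(1 / 8, 8))
  expect_equal(length(W$neighbors[[corner]]), 3)
  expect_equal(W$weights[[corner]], rep(1 / 3, 3))
  expect_false(any(vapply(seq_len(9), function(i)
    i %in% W$neighbors[[i]], logical(1))))  # w_ii = 0

  # binary adjacency symmetric before row-standardization
  for (i in seq_len(9)) for (j in W$neighbors[[i]])
    expect_true(i %in% W$neighbors[[j]])

  # rook: 4 neighbors in the middle
  Wr <- build_weights(grid, "rook")
  expect_equal(length(Wr$neighbors[[center]]), 4)
})

test_that("bivariate local Moran matches the formula oracle", {
  grid <- lattice_grid(3, 3)
  W <- build_weights(grid, "queen")
  x <- as.numeric(1:9)
  y <- rev(x)
  lm <- bivariate_local_moran(x, y, W)
  # independent direct evaluation
  zx <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  zy <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
  oracle <- vapply(1:9, function(i)
    zx[i] * sum(W$weights[[i]] * zy[W$neighbors[[i]]]), numeric(1))
  expect_equal(lm$I, oracle, tolerance = 1e-12)

  # mean of local I equals the direct global cross-statistic
  Wmat <- matrix(0, 9, 9)
  for (i in 1:9) Wmat[i, W$neighbors[[i]]] <- W$weights[[i]]
  expect_equal(mean(lm$I), as.numeric(zx %*% Wmat %*% zy) / 9,
               tolerance = 1e-12)

  # constant x or y: the statistic is identically zero (warned about as
  # degenerate; strict mode raises instead, naming the variable)
  expect_warning(lm_cx <- bivariate_local_moran(rep(1, 9), y, W),
                 "zero variance in x")
  expect_equal(lm_cx$I, rep(0, 9))
  expect_warning(lm_cy <- bivariate_local_moran(x, rep(2, 9), W),
                 "zero variance in y")
  expect_equal(lm_cy$I, rep(0, 9))
  expect_error(bivariate_local_moran(rep(1, 9), y, W,
                                     on_degenerate = "error"),
               "zero variance in x")

  # affine rescaling of x and y leaves I unchanged
  lm2 <- bivariate_local_moran(3 * x + 10, -0.5 * y + 4, W)
  expect_equal(abs(lm2$I), abs(oracle), tolerance = 1e-12)
  lm3 <- bivariate_local_moran(3 * x + 10, 0.5 * y + 4, W)
  expect_equal(lm3$I, oracle, tolerance = 1e-12)
})

test_that("permutation p-values are seeded, bounded, and calibrated", {
  grid <- lattice_grid(5, 5)
  W <- build_weights(grid)
  set.seed(41)
  x <- rnorm(25); y <- rnorm(25)
  p1 <- permutation_pvalues(x, y, W, n_perm = 99, seed = 5)
  p2 <- permutation_pvalues(x, y, W, n_perm = 99, seed = 5)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 1 / 100 & p1 <= 1))

  # extreme-rank bound: an I larger than every permutation gets 1/(n+1)
  x2 <- rep(0, 25); x2[13] <- 50
  y2 <- rnorm(25)
  # force cell 13's observed lag to exceed anything a permutation can give
  y2[W$neighbors[[13]]] <- 100
  p <- permutation_pvalues(x2, y2, W, n_perm = 99, seed = 1)
  expect_equal(p[13], 1 / 100)
})

test_that("conditional permutation keeps type-I error near alpha", {
  grid <- lattice_grid(20, 20)
  W <- build_weights(grid)
  set.seed(42)
  x <- rnorm(400); y <- rnorm(400)
  p <- permutation_pvalues(x, y, W, n_perm = 999, seed = 7)
  rej <- mean(p < 0.05)
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.08)
})

test_that("classification respects its defining inequalities", {
  I <- c(2.1, -1.8, 0.4, NA)
  p <- c(0.01, 0.02, 0.40, NA)
  cls <- classify_cells(I, p, alpha = 0.05)
  expect_equal(cls, c("hotspot", "diffusion", "nonsignificant", "isolated"))
  expect_error(classify_cells(I, p, alpha = 1.2), "alpha")

  # invariants on a random field
  grid <- lattice_grid(6, 6)
  W <- build_weights(grid)
  set.seed(43)
  x <- rexp(36); y <- rexp(36)
  lm <- bivariate_local_moran(x, y, W)
  pv <- permutation_pvalues(x, y, W, n_perm = 199, seed = 2)
  cls <- classify_cells(lm$I, pv, 0.05, isolated = rep(FALSE, 36))
  expect_true(all(lm$I[cls == "hotspot"] > 0))
  expect_true(all(pv[cls == "hotspot"] < 0.05))
  expect_true(all(lm$I[cls == "diffusion"] < 0))
  expect_true(all(pv[cls == "diffusion"] < 0.05))
})

test_that("lisa_field runs end to end on simulated surveillance", {
  cfg <- tiny_sim_config(seed = 51)
  sim <- simulate_surveillance(cfg)
  lab <- assign_landuse(standardize_tubes(sim$tubes), sim$map)
  lf <- lisa_field(lab[lab$year == 2010, ], lab[lab$year == 2011, ],
                   source_code = "030101", cell_size_m = 500,
                   extent = sim$map$extent, n_perm = 199, seed = 3)
  expect_true(all(c("I", "pseudo_p", "class") %in% names(lf)))
  expect_true(all(lf$class %in% c("hotspot", "diffusion",
                                  "nonsignificant", "isolated")))
  expect_equal(nrow(lf), 36)  # 6 x 6 cells of 500 m over 3 km
})
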