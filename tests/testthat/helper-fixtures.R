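# Fixtures built in code: tiny maps, tube tables and configs shared
# across tests.

# Two adjacent unit-km squares sharing the edge x = 1000: paddy (west)
# and road (east).
two_patch_map <- function() {
  ring <- function(x0, y0, x1, y1) {
    matrix(c(x0, y0, x1, y0, x1, y1, x0, y1, x0, y0), ncol = 2,
           byrow = TRUE, dimnames = list(NULL, c("x", "y")))
  }
  landuse_map(list(
    list(outer = ring(0, 0, 1000, 1000), holes = list(),
         code_l1 = "010000", code_l2 = "010100", code_l3 = "010101",
         label = "paddy field"),
    list(outer = ring(1000, 0, 2000, 1000), holes = list(),
         code_l1 = "030000", code_l2 = "030100", code_l3 = "030101",
         label = "main road")))
}

# Donut: 1-km square with a central square hole.
holey_map <- function() {
  outer <- matrix(c(0, 0, 1000, 0, 1000, 1000, 0, 1000, 0, 0),
                  ncol = 2, byrow = TRUE)
  hole <- matrix(c(400, 400, 600, 400, 600, 600, 400, 600, 400, 400),
                 ncol = 2, byrow = TRUE)
  landuse_map(list(
    list(outer = outer, holes = list(hole),
         code_l1 = "090000", code_l2 = "090100", code_l3 = "090101",
         label = "grassland")))
}

make_tubes <- function(x, y, year = 2008, status = 1L, spacing = 200,
                       id = NULL) {
  n <- length(x)
  data.frame(tube_id = id %||% sprintf("T%03d", seq_len(n)),
             x = x, y = y, year = rep_len(year, n),
             status = as.integer(rep_len(status, n)),
             grid_spacing_m = rep_len(spacing, n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small, fast simulation for end-to-end tests: 3 x 3 km, 4 years.
tiny_sim_config <- function(seed = 1L, ...) {
  simulation_config(
    extent = c(0, 0, 3000, 3000), years = 2008:2011,
    landuse_spec = list(n_patch_seeds = 36, n_roads = 2,
                        n_warehouses = 4),
    ...,
    seed = seed)
}

# Direct modularity of a partition on a symmetrized weighted graph
# (independent oracle for community detection).
modularity_oracle <- function(W_sym, membership) {
  # W_sym: symmetric weight matrix with self-loops on the diagonal
  k <- rowSums(W_sym)
  two_m <- sum(W_sym)
  same <- outer(membership, membership, "==")
  sum((W_sym - outer(k, k) / two_m) * same) / two_m
}
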