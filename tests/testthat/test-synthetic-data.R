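test_that("landscape generation is seeded-deterministic and gap-free", {
  cfg <- tiny_sim_config(seed = 11)
  m1 <- generate_landuse_map(cfg)
  m2 <- generate_landuse_map(cfg)
  expect_identical(m1, m2)

  # exact coverage: polygon areas sum to the extent area
  total <- sum(landuse_areas(m1)$area_m2)
  ext_area <- (cfg$extent[3] - cfg$extent[1]) *
    (cfg$extent[4] - cfg$extent[2])
  expect_lt(abs(total - ext_area), 1e-6)

  # every interior sample point is classified by exactly one polygon
  set.seed(1)
  px <- runif(500, 1, 2999); py <- runif(500, 1, 2999)
  expect_false(anyNA(landuse_at(px, py, m1)))

  # required types all present
  codes <- vapply(m1$polygons, `[[`, character(1), "label")
  expect_true(all(c("paddy field", "main road", "warehouse") %in% codes))
  # each level-III code maps to a single level-II and level-I parent
  h <- landuse_areas(m1)
  hier <- unique(data.frame(
    l3 = vapply(m1$polygons, `[[`, character(1), "code_l3"),
    l2 = vapply(m1$polygons, `[[`, character(1), "code_l2"),
    l1 = vapply(m1$polygons, `[[`, character(1), "code_l1")))
  expect_false(any(duplicated(hier$l3)))
})

test_that("patch type proportions are honored empirically", {
  cfg <- simulation_config(
    extent = c(0, 0, 4000, 4000),
    landuse_spec = list(type_props = c(paddy = 0.4, upland = 0.2,
                                       residential = 0.2, grassland = 0.2),
                        n_roads = 2, road_buffer_m = 30,
                        n_warehouses = 2),
    seed = 5)
  m <- generate_landuse_map(cfg)
  set.seed(99)
  px <- runif(10000, 0, 4000); py <- runif(10000, 0, 4000)
  share <- mean(landuse_at(px, py, m) == "010101")
  expect_lt(abs(share - 0.4), 0.05)
})

test_that("tube schedules form lattices with correct counts and tags", {
  ext <- c(0, 0, 1000, 1000)
  sched <- list(`2008` = data.frame(xmin = 0, ymin = 0, xmax = 1000,
                                    ymax = 1000, spacing_m = 200),
                `2009` = data.frame(xmin = c(0, 600), ymin = 0,
                                    xmax = c(600, 1000), ymax = c(600, 600),
                                    spacing_m = c(100, 200)))
  cfg <- simulation_config(extent = ext, years = 2008:2009,
                           tube_spacing_schedule = sched, seed = 1)
  tubes <- generate_tube_schedule(cfg)
  y1 <- tubes[tubes$year == 2008, ]
  expect_equal(nrow(y1), 25)  # 5 x 5 lattice
  expect_setequal(unique(y1$x), 200 * (1:5) - 100)

  y2 <- tubes[tubes$year == 2009, ]
  # each tube's spacing matches its containing zone
  in_zone1 <- y2$x < 600
  expect_true(all(y2$grid_spacing_m[in_zone1] == 100))
  expect_true(all(y2$grid_spacing_m[!in_zone1] == 200))

  # single-cell zone: one tube at the center
  sched1 <- list(`2008` = data.frame(xmin = 0, ymin = 0, xmax = 600,
                                     ymax = 600, spacing_m = 600),
                 `2009` = data.frame(xmin = 0, ymin = 0, xmax = 600,
                                     ymax = 600, spacing_m = 600))
  cfg1 <- simulation_config(extent = c(0, 0, 600, 600), years = 2008:2009,
                            tube_spacing_schedule = sched1, seed = 1)
  t1 <- generate_tube_schedule(cfg1)
  expect_equal(nrow(t1[t1$year == 2008, ]), 1)
  expect_equal(t1$x[1], 300)
  expect_equal(t1$y[1], 300)
})

test_that("overlapping zones within a year are rejected", {
  sched <- list(`2008` = data.frame(xmin = c(0, 100), ymin = c(0, 100),
                                    xmax = c(500, 600), ymax = c(500, 600),
                                    spacing_m = c(200, 200)),
                `2009` = data.frame(xmin = 0, ymin = 0, xmax = 600,
                                    ymax = 600, spacing_m = 200))
  expect_error(
    simulation_config(extent = c(0, 0, 600, 600), years = 2008:2009,
                      tube_spacing_schedule = sched),
    "overlapping")
})

test_that("infestation dynamics honor the kernel and detection rules", {
  cfg <- tiny_sim_config(seed = 3)
  map <- generate_landuse_map(cfg)
  tubes <- generate_tube_schedule(cfg)
  sim <- simulate_infestation(map, tubes, cfg)

  # determinism
  sim2 <- simulate_infestation(map, tubes, cfg)
  expect_identical(sim, sim2)

  # all positive tubes lie within detection_radius_m of an active focus
  for (yr in cfg$years) {
    pos <- sim$tubes[sim$tubes$year == yr & sim$tubes$status == 1L, ]
    act <- sim$foci[sim$foci$year_established <= yr, ]
    if (nrow(pos) > 0) {
      d <- antspread:::min_dist_to_set(pos$x, pos$y, act$x, act$y)
      expect_true(all(d <= cfg$detection_radius_m))
    }
    neg <- sim$tubes[sim$tubes$year == yr & sim$tubes$status == 0L, ]
    d <- antspread:::min_dist_to_set(neg$x, neg$y, act$x, act$y)
    expect_true(all(d > cfg$detection_radius_m))
  }

  # initial foci sit on the source land-use type
  init <- sim$foci[sim$foci$year_established == cfg$years[1], ]
  expect_equal(nrow(init), cfg$n_initial_foci)
  expect_true(all(init$landuse_code == cfg$initial_landuse_code))
})

test_that("zero offspring rate freezes the infestation", {
  cfg <- tiny_sim_config(seed = 4, offspring_rate = 0)
  sim <- simulate_surveillance(cfg)
  expect_equal(nrow(sim$foci), cfg$n_initial_foci)
  # the same locations are positive every year (lattices differ between
  # years, so compare detected focus sets instead of tube ids)
  expect_true(all(sim$foci$year_established == cfg$years[1]))
})

test_that("p_near = 1 bounds all displacements by d0", {
  cfg <- tiny_sim_config(seed = 5,
                         kernel = list(d0 = 600, p_near = 1, d_max = 3000))
  sim <- simulate_surveillance(cfg)
  expect_gt(length(sim$displacements), 0)
  expect_true(all(sim$displacements <= 600))
  d_est <- sim$foci$displacement_m[!is.na(sim$foci$displacement_m)]
  expect_true(all(d_est <= 600))
})

test_that("kernel quantile: P(D <= d0) matches p_near at large n", {
  cfg <- tiny_sim_config(seed = 6, offspring_rate = 30,
                         suitability = c(default = 0.3))
  sim <- simulate_surveillance(cfg)
  d <- sim$displacements
  expect_gt(length(d), 10000)
  p_hat <- mean(d <= 600)
  tol <- 3 * sqrt(0.75 * 0.25 / length(d))
  expect_lt(abs(p_hat - 0.75), tol)
})

test_that("zero-suitability land uses host no established foci", {
  cfg <- tiny_sim_config(
    seed = 7,
    suitability = c(default = 0.8, `010101` = 0))
  sim <- simulate_surveillance(cfg)
  established <- sim$foci[sim$foci$year_established > cfg$years[1], ]
  expect_false(any(established$landuse_code == "010101"))
})

test_that("full generator run is reproducible end to end", {
  cfg <- tiny_sim_config(seed = 8)
  s1 <- simulate_surveillance(cfg)
  s2 <- simulate_surveillance(cfg)
  expect_identical(s1$tubes, s2$tubes)
  expect_identical(s1$foci, s2$foci)
  expect_identical(s1$map, s2$map)
})
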