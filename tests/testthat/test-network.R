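test_that("land-use assignment is containment with a deterministic boundary rule", {
  map <- two_patch_map()
  tubes <- make_tubes(x = c(500, 1500, 5000, 1000), y = c(500, 500, 500, 500))
  lab <- assign_landuse(tubes, map)
  expect_equal(lab$landuse_code[1], "010101")  # strictly inside paddy
  expect_equal(lab$landuse_code[2], "030101")  # strictly inside road
  expect_true(lab$unclassified[3])             # outside all polygons
  # point exactly on the shared edge: lexicographically smaller code wins
  expect_equal(lab$landuse_code[4], "010101")
  # stable across repeated evaluation
  for (r in 1:3)
    expect_identical(assign_landuse(tubes, map)$landuse_code,
                     lab$landuse_code)
})

test_that("points inside a map hole are unclassified", {
  map <- holey_map()
  lab <- assign_landuse(make_tubes(x = c(500, 100), y = c(500, 100)), map)
  expect_true(lab$unclassified[1])   # in the hole
  expect_false(lab$unclassified[2])  # in the ring
})

test_that("transition networks split target mass among in-range sources", {
  src <- data.frame(x = c(0, 0), y = c(0, 600), landuse_code = c("A", "B"),
                    weight = c(1, 1), stringsAsFactors = FALSE)
  tgt <- data.frame(x = 0, y = 300, landuse_code = "C", weight = 1,
                    stringsAsFactors = FALSE)

  # single pair: one edge with the full target weight
  net1 <- build_transition_network(src[1, ], tgt, d_star = 600)
  expect_equal(net1$edges,
               data.frame(src_code = "A", dst_code = "C", weight = 1))

  # two in-range sources: mass split half-and-half
  net2 <- build_transition_network(src, tgt, d_star = 600)
  expect_equal(net2$edges$weight, c(0.5, 0.5))
  expect_setequal(net2$edges$src_code, c("A", "B"))

  # all pairs out of range: empty network is valid
  net0 <- build_transition_network(src, tgt, d_star = 100)
  expect_equal(nrow(net0$edges), 0)

  # count mode: each qualifying pair contributes one
  netc <- build_transition_network(src, tgt, d_star = 600, mode = "count")
  expect_equal(netc$edges$weight, c(1, 1))
})

test_that("transition networks conserve attributed target mass", {
  set.seed(31)
  for (rep in 1:5) {
    n_s <- sample(20:60, 1); n_t <- sample(20:60, 1)
    src <- data.frame(x = runif(n_s, 0, 3000), y = runif(n_s, 0, 3000),
                      landuse_code = sample(LETTERS[1:5], n_s, TRUE),
                      weight = sample(c(0.25, 1, 9), n_s, TRUE))
    tgt <- data.frame(x = runif(n_t, 0, 3000), y = runif(n_t, 0, 3000),
                      landuse_code = sample(LETTERS[1:5], n_t, TRUE),
                      weight = sample(c(0.25, 1, 9), n_t, TRUE))
    net <- build_transition_network(src, tgt, d_star = 600)
    # oracle: summed weight of targets with at least one in-range source
    has_src <- vapply(seq_len(n_t), function(j)
      any((src$x - tgt$x[j])^2 + (src$y - tgt$y[j])^2 <= 600^2),
      logical(1))
    expect_equal(sum(net$edges$weight), sum(tgt$weight[has_src]),
                 tolerance = 1e-12)
  }
})

test_that("HITS matches closed forms and an eigenvector oracle", {
  edge_net <- function(edges) {
    nodes <- sort(unique(c(edges$src_code, edges$dst_code)))
    structure(list(edges = edges, nodes = nodes, year_pair = NULL,
                   mode = "split"), class = "transition_network")
  }
  # single edge A -> B
  hs <- hits_scores(edge_net(data.frame(
    src_code = "A", dst_code = "B", weight = 2.5)))
  expect_equal(hs$hub[hs$code == "A"], 1)
  expect_equal(hs$hub[hs$code == "B"], 0)
  expect_equal(hs$authority[hs$code == "B"], 1)
  expect_equal(hs$hub_rank[hs$code == "A"], 1L)

  # two symmetric sources into one sink: hubs 1/sqrt(2)
  hs2 <- hits_scores(edge_net(data.frame(
    src_code = c("A", "B"), dst_code = "C", weight = c(1, 1))))
  expect_equal(hs2$hub[hs2$code %in% c("A", "B")],
               rep(1 / sqrt(2), 2), tolerance = 1e-12)

  # random weighted digraphs vs principal eigenvector of W W^T
  set.seed(32)
  for (rep in 1:20) {
    n_e <- sample(8:20, 1)
    edges <- unique(data.frame(
      src_code = sample(LETTERS[1:6], n_e, TRUE),
      dst_code = sample(LETTERS[1:6], n_e, TRUE),
      stringsAsFactors = FALSE))
    edges$weight <- runif(nrow(edges), 0.1, 5)
    net <- edge_net(edges)
    hs <- hits_scores(net)
    W <- antspread:::network_matrix(net)
    eig <- eigen(W %*% t(W), symmetric = TRUE)
    v <- eig$vectors[, 1]
    v <- abs(v) / sqrt(sum(v^2))  # sign-aligned principal eigenvector
    expect_equal(hs$hub[match(net$nodes, hs$code)], v, tolerance = 1e-8)
    # unit norms, non-negative entries
    expect_equal(sum(hs$hub^2), 1, tolerance = 1e-10)
    expect_equal(sum(hs$authority^2), 1, tolerance = 1e-10)
    expect_true(all(hs$hub >= -1e-12 & hs$authority >= -1e-12))
    # invariance under uniform scaling of all edge weights
    edges2 <- edges; edges2$weight <- edges2$weight * 7.7
    hs_s <- hits_scores(edge_net(edges2))
    expect_equal(hs_s$hub, hs$hub, tolerance = 1e-8)
  }

  empty <- edge_net(data.frame(src_code = character(0),
                               dst_code = character(0),
                               weight = numeric(0)))
  expect_error(hits_scores(empty), "no edges")
})

test_that("community detection recovers disconnected cliques and honest modularity", {
  tri <- function(nodes, w = 1) data.frame(
    src_code = nodes, dst_code = nodes[c(2, 3, 1)], weight = w,
    stringsAsFactors = FALSE)
  edges <- rbind(tri(c("A", "B", "C")), tri(c("D", "E", "F")))
  net <- structure(list(edges = edges,
                        nodes = sort(unique(c(edges$src_code,
                                              edges$dst_code))),
                        year_pair = NULL, mode = "split"),
                   class = "transition_network")
  cm <- detect_communities(net, seed = 1)
  expect_equal(length(unique(cm$community)), 2)
  expect_equal(length(unique(cm$community[cm$code %in% c("A", "B", "C")])), 1)
  expect_equal(length(unique(cm$community[cm$code %in% c("D", "E", "F")])), 1)

  # modularity of the returned partition: formula oracle + >= singletons
  W <- antspread:::network_matrix(net)
  S <- W + t(W)
  q <- network_modularity(net, cm$community)
  expect_equal(q, modularity_oracle(S, cm$community), tolerance = 1e-9)
  q_single <- network_modularity(net, seq_along(net$nodes))
  expect_gte(q, q_single)

  # igraph cross-check on a loop-free graph (conventions coincide)
  expect_equal(q, igraph::modularity(
    igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                        weighted = TRUE),
    cm$community, weights = NULL), tolerance = 1e-12)

  # random networks: partition modularity always matches the oracle
  set.seed(33)
  for (rep in 1:5) {
    e <- unique(data.frame(
      src_code = sample(LETTERS[1:8], 15, TRUE),
      dst_code = sample(LETTERS[1:8], 15, TRUE),
      stringsAsFactors = FALSE))
    e$weight <- runif(nrow(e), 0.2, 4)
    netr <- structure(list(edges = e,
                           nodes = sort(unique(c(e$src_code, e$dst_code))),
                           year_pair = NULL, mode = "split"),
                      class = "transition_network")
    cmr <- detect_communities(netr, seed = rep)
    Sr <- antspread:::network_matrix(netr)
    Sr <- Sr + t(Sr)
    qr <- network_modularity(netr, cmr$community)
    expect_equal(qr, modularity_oracle(Sr, cmr$community), tolerance = 1e-9)
    expect_gte(qr, network_modularity(netr, seq_along(netr$nodes)) - 1e-12)
  }

  # single isolated node: one community
  net1 <- structure(list(edges = data.frame(src_code = "A",
                                            dst_code = "A", weight = 1),
                         nodes = "A", year_pair = NULL, mode = "split"),
                    class = "transition_network")
  expect_equal(detect_communities(net1)$community, 1L)
})
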