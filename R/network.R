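#' Assign land-use codes to tubes
#'
#' Point-in-polygon spatial join of a tube table against a land-use map.
#' Boundary points go to the polygon with the lexicographically smallest
#' level-III code (deterministic); tubes falling in no polygon get `NA`
#' (`unclassified = TRUE`).
#'
#' @param tubes data.frame with `x`, `y` (planar meters, same CRS as the
#'   map).
#' @param map a [landuse_map()].
#' @return the input with `landuse_code` (level-III) and `unclassified`
#'   columns appended.
#' @export
assign_landuse <- function(tubes, map) {
  stopifnot(is.data.frame(tubes), all(c("x", "y") %in% names(tubes)))
  tubes$landuse_code <- landuse_at(tubes$x, tubes$y, map)
  tubes$unclassified <- is.na(tubes$landuse_code)
  tubes
}

#' Land-use transition network for one year pair
#'
#' Nodes are level-III land-use codes; a directed edge src -> dst
#' accumulates the diffusion mass attributed from year-t positives of
#' code src to year-t+1 positives of code dst. Only source tubes within
#' the critical dispersal distance `d_star` of a target qualify. Each
#' target's standardized weight is split equally among its in-range
#' sources (`mode = "split"`, mass-conserving: total edge weight equals
#' the summed weight of attributed targets), or each in-range pair
#' counts 1 (`mode = "count"`). Unclassified tubes are excluded.
#'
#' @param labeled_t,labeled_t1 classified positive tubes
#'   ([assign_landuse()] + [standardize_tubes()]) for years t and t+1.
#' @param d_star attribution radius (m), typically the critical
#'   dispersal distance.
#' @param year_pair optional `c(t, t1)` annotation.
#' @param mode `"split"` (default) or `"count"`.
#' @return list of class `transition_network`: `edges` (data.frame
#'   `src_code, dst_code, weight`), `nodes`, `year_pair`, `mode`. An
#'   empty edge set is a valid network.
#' @export
build_transition_network <- function(labeled_t, labeled_t1, d_star,
                                     year_pair = NULL,
                                     mode = c("split", "count")) {
  mode <- match.arg(mode)
  if (d_star <= 0) stop("d_star must be > 0")
  src <- labeled_t[!is.na(labeled_t$landuse_code), , drop = FALSE]
  tgt <- labeled_t1[!is.na(labeled_t1$landuse_code), , drop = FALSE]
  edges <- data.frame(src_code = character(0), dst_code = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  if (nrow(src) > 0 && nrow(tgt) > 0) {
    tgt_w <- if ("weight" %in% names(tgt)) tgt$weight else rep(1, nrow(tgt))
    acc <- new.env(parent = emptyenv())
    d2max <- d_star^2
    for (j in seq_len(nrow(tgt))) {
      d2 <- (src$x - tgt$x[j])^2 + (src$y - tgt$y[j])^2
      in_range <- which(d2 <= d2max)
      if (length(in_range) == 0) next
      contrib <- if (mode == "split")
        tgt_w[j] / length(in_range) else 1
      for (i in in_range) {
        key <- paste(src$landuse_code[i], tgt$landuse_code[j], sep = "\r")
        prev <- if (is.null(acc[[key]])) 0 else acc[[key]]
        acc[[key]] <- prev + contrib
      }
    }
    keys <- ls(acc)
    if (length(keys) > 0) {
      parts <- strsplit(keys, "\r", fixed = TRUE)
      edges <- data.frame(
        src_code = vapply(parts, `[`, character(1), 1),
        dst_code = vapply(parts, `[`, character(1), 2),
        weight = vapply(keys, function(k) acc[[k]], numeric(1)),
        stringsAsFactors = FALSE)
      edges <- edges[order(edges$src_code, edges$dst_code), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  nodes <- sort(unique(c(edges$src_code, edges$dst_code)))
  structure(list(edges = edges, nodes = nodes, year_pair = year_pair,
                 mode = mode),
            class = "transition_network")
}

#' @export
print.transition_network <- function(x, ...) {
  yp <- if (is.null(x$year_pair)) "" else
    sprintf(" (%s-%s)", x$year_pair[1], x$year_pair[2])
  cat(sprintf("transition_network%s: %d nodes, %d edges, total weight %.4g\n",
              yp, length(x$nodes), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

# Dense weight matrix of a transition network (rows = source nodes).
network_matrix <- function(net) {
  n <- length(net$nodes)
  W <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0)
    W[cbind(match(net$edges$src_code, net$nodes),
            match(net$edges$dst_code, net$nodes))] <- net$edges$weight
  W
}

#' HITS hub and authority scores
#'
#' Weighted HITS power iteration on the directed transition network:
#' authorities a <- W'h, hubs h <- W a, with Euclidean normalization at
#' each step, iterated to convergence. High-hub land-use types send
#' diffusion mass to strong receivers and are read as diffusion sources.
#' Ranks are by descending hub value, ties broken by code order.
#'
#' @param net a [build_transition_network()] result with >= 1 edge.
#' @param tol convergence tolerance on the max absolute change.
#' @param max_iter iteration cap; exceeding it is an error.
#' @return data.frame `code, hub, authority, hub_rank`; hub and
#'   authority vectors each have unit Euclidean norm.
#' @export
hits_scores <- function(net, tol = 1e-12, max_iter = 1000) {
  if (nrow(net$edges) == 0) stop("network has no edges")
  W <- network_matrix(net)
  n <- nrow(W)
  h <- rep(1 / sqrt(n), n)
  a <- rep(0, n)
  for (it in seq_len(max_iter)) {
    a_new <- as.vector(crossprod(W, h))
    a_new <- a_new / sqrt(sum(a_new^2))
    h_new <- as.vector(W %*% a_new)
    h_new <- h_new / sqrt(sum(h_new^2))
    if (max(abs(h_new - h)) < tol && max(abs(a_new - a)) < tol) {
      h <- h_new; a <- a_new
      out <- data.frame(code = net$nodes, hub = h, authority = a,
                        stringsAsFactors = FALSE)
      out$hub_rank <- rank_by_desc(out$hub, out$code)
      return(out)
    }
    h <- h_new; a <- a_new
  }
  stop("HITS did not converge within ", max_iter, " iterations")
}

# Dense rank by descending score, ties broken by ascending key.
rank_by_desc <- function(score, key) {
  ord <- order(-score, key)
  r <- integer(length(score))
  r[ord] <- seq_along(score)
  r
}

#' Louvain communities of the transition network
#'
#' Runs Louvain modularity optimization (Blondel et al.'s multi-level
#' method, via igraph) on the symmetrized weighted graph: each
#' undirected edge weight is the sum of both directed weights and
#' self-loops are retained. Land-use types in one community exchange
#' diffusion mass intensively; diffusion between communities is rare.
#'
#' @param net a [build_transition_network()] result.
#' @param resolution Louvain resolution parameter.
#' @param seed RNG seed (community detection is seeded for
#'   reproducibility).
#' @return data.frame `code, community` (contiguous integer labels).
#' @export
detect_communities <- function(net, resolution = 1.0, seed = 1L) {
  if (length(net$nodes) == 0) stop("empty network")
  W <- network_matrix(net)
  S <- W + t(W)
  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                           weighted = TRUE, diag = TRUE)
  set.seed(seed)
  memb <- if (igraph::ecount(g) == 0) {
    seq_along(net$nodes)
  } else {
    as.integer(igraph::membership(
      igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                              resolution = resolution)))
  }
  memb <- match(memb, unique(memb))  # contiguous labels
  data.frame(code = net$nodes, community = memb, stringsAsFactors = FALSE)
}

#' Modularity of a node partition
#'
#' Newman-Girvan modularity of a community assignment, evaluated on the
#' same symmetrized weighted graph community detection runs on
#' (undirected weight = sum of both directed weights; self-loops kept on
#' the diagonal): Q = (1/2m) * sum_ij (w_ij - k_i k_j / 2m) *
#' delta(c_i, c_j) with k_i = sum_j w_ij and 2m = sum_ij w_ij.
#'
#' @param net a [build_transition_network()] result.
#' @param membership community labels in node order (e.g. from
#'   [detect_communities()]).
#' @return the modularity Q.
#' @export
network_modularity <- function(net, membership) {
  if (length(membership) != length(net$nodes))
    stop("membership must have one label per node")
  W <- network_matrix(net)
  S <- W + t(W)
  k <- rowSums(S)
  two_m <- sum(S)
  if (two_m <= 0) return(0)
  same <- outer(membership, membership, "==")
  sum((S - outer(k, k) / two_m) * same) / two_m
}

#' Combined node scores
#'
#' Hub/authority scores, hub ranks and community labels in one table
#' (the layout used to report diffusion sources per year pair).
#'
#' @inheritParams hits_scores
#' @inheritParams detect_communities
#' @param labels optional named character vector mapping codes to
#'   human-readable labels.
#' @return data.frame `code, label, hub, authority, hub_rank, community`.
#' @export
score_nodes <- function(net, labels = NULL, tol = 1e-12, max_iter = 1000,
                        resolution = 1.0, seed = 1L) {
  hs <- hits_scores(net, tol, max_iter)
  cm <- detect_communities(net, resolution, seed)
  out <- merge(hs, cm, by = "code", sort = TRUE)
  out$label <- if (is.null(labels)) NA_character_ else
    unname(labels[out$code])
  out[order(out$hub_rank),
      c("code", "label", "hub", "authority", "hub_rank", "community")]
}
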