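#' Default run configuration
#'
#' Builds the `run_config` list consumed by [run_pipeline()]. Exactly
#' one data source must be active: a simulation block (a
#' [simulation_config()] or argument list for one) or a pair of input
#' paths (`tubes` CSV + `landuse` GeoJSON). All stage parameters carry
#' explicit defaults and every stochastic stage takes its seed from
#' here, so a rerun with the same config reproduces artifacts exactly.
#'
#' @param simulation a [simulation_config()], or a list of arguments for
#'   one, or `NULL` when reading files.
#' @param inputs list `tubes = <csv>, landuse = <geojson>` or `NULL`.
#' @param stages character subset of
#'   `c("standardize", "surface", "distance", "network", "lisa")`.
#' @param params list of stage parameters; see Details for defaults.
#' @param out_dir output directory (`NULL` = no files written).
#'
#' @details Parameter defaults: `reference_m = 200` (standardization),
#' `surface_cell_m = 250` and `variogram_family = "spherical"`
#' (kriging), `bin_width_m = 50` and `weighted = TRUE` (dispersal
#' curves), `d_star_override = NULL` (network radius; `NULL` = use the
#' estimated mean critical distance), `source_code = NULL` (LISA source
#' type; `NULL` = the top-hub code of the first year pair),
#' `lisa_cell_m = 500`, `n_perm = 999`, `alpha = 0.05`, `seed = 1`.
#' @return list of class `run_config`.
#' @export
run_config <- function(simulation = NULL, inputs = NULL,
                       stages = c("standardize", "surface", "distance",
                                  "network", "lisa"),
                       params = list(), out_dir = NULL) {
  if (is.null(simulation) == is.null(inputs))
    stop("exactly one of `simulation` or `inputs` must be given")
  defaults <- list(reference_m = 200, surface_cell_m = 250,
                   variogram_family = "spherical", bin_width_m = 50,
                   weighted = TRUE, d_star_override = NULL,
                   source_code = NULL, lisa_cell_m = 500,
                   n_perm = 999, alpha = 0.05, seed = 1L)
  params <- utils::modifyList(defaults, params)
  if (!is.null(simulation) && !inherits(simulation, "simulation_config"))
    simulation <- do.call(simulation_config, simulation)
  structure(list(simulation = simulation, inputs = inputs,
                 stages = stages, params = params, out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The YAML mirrors [run_config()]: top-level `simulation` or `inputs`,
#' optional `stages`, `params`, `out_dir`.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(simulation = y$simulation, inputs = y$inputs,
             stages = y$stages %||% c("standardize", "surface", "distance",
                                      "network", "lisa"),
             params = y$params %||% list(), out_dir = y$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small dependency-free content hash for the manifest: a polynomial
# rolling hash mod a prime below 2^26 (all arithmetic exact in doubles).
content_hash <- function(raw_bytes) {
  m <- 67108859
  h <- 17
  for (b in as.integer(raw_bytes)) h <- (h * 31 + b) %% m
  sprintf("%08x", h)
}

hash_file <- function(path) content_hash(readBin(path, "raw",
                                                 file.info(path)$size))

#' Run the full diffusion-analysis pipeline
#'
#' Orchestrates, in dependency order, the enabled stages: data (simulate
#' or read), density standardization, land-use assignment, kriged
#' intensity surfaces per year, consecutive-year dispersal curves and
#' critical distances, land-use transition networks with HITS/community
#' scores, and the bivariate LISA hotspot/diffusion fields. When
#' `out_dir` is set, every artifact is written (CSV / GeoJSON /
#' ESRI-ASCII / GEXF) together with a `manifest.json` echoing the
#' configuration, seeds and input hashes; identical config + seed yields
#' identical artifacts.
#'
#' @param config a [run_config()] or path to a YAML config.
#' @return list of artifacts: `tubes`, `map`, `foci` (simulation only),
#'   `weighted`, `labeled`, `incidence`, `surfaces`, `curves`,
#'   `critical`, `mean_d_star`, `networks`, `scores`, `lisa`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  art <- list()
  input_hashes <- list()

  # --- data stage -----------------------------------------------------
  if (!is.null(config$simulation)) {
    sim <- simulate_surveillance(config$simulation)
    tubes <- sim$tubes; map <- sim$map
    art$foci <- sim$foci
  } else {
    tubes <- read_tubes(config$inputs$tubes)
    map <- read_landuse(config$inputs$landuse)
    input_hashes <- list(tubes = hash_file(config$inputs$tubes),
                         landuse = hash_file(config$inputs$landuse))
  }
  art$tubes <- tubes; art$map <- map
  years <- sort(unique(tubes$year))

  # --- standardization + land-use assignment --------------------------
  labeled <- NULL
  if ("standardize" %in% config$stages) {
    weighted <- standardize_tubes(tubes, p$reference_m)
    labeled <- assign_landuse(weighted, map)
    art$weighted <- weighted
    art$labeled <- labeled
    art$incidence <- incidence_table(labeled, "year")
  }
  need_labeled <- function(stage) {
    if (is.null(labeled))
      stop("stage '", stage, "' requires the standardize stage")
    labeled
  }
  pos_year <- function(yr) {
    l <- need_labeled("year split")
    l[l$year == yr & l$status == 1L, , drop = FALSE]
  }

  # --- kriged intensity surfaces --------------------------------------
  if ("surface" %in% config$stages) {
    l <- need_labeled("surface")
    art$surfaces <- stats::setNames(lapply(years, function(yr) {
      krige_intensity(l[l$year == yr, , drop = FALSE],
                      cell_size_m = p$surface_cell_m,
                      family = p$variogram_family)
    }), as.character(years))
  }

  # --- dispersal curves and critical distances ------------------------
  if ("distance" %in% config$stages) {
    need_labeled("distance")
    pairs <- lapply(seq_len(length(years) - 1),
                    function(i) c(years[i], years[i + 1]))
    art$curves <- list(); art$critical <- list()
    for (pr in pairs) {
      key <- paste(pr, collapse = "_")
      cd <- critical_distance(pos_year(pr[1]), pos_year(pr[2]),
                              p$bin_width_m, p$weighted)
      art$curves[[key]] <- cd$curve
      art$critical[[key]] <- cd
    }
    art$mean_d_star <- mean_critical_distance(
      vapply(art$critical, `[[`, numeric(1), "d_star"))
  }

  # --- transition networks --------------------------------------------
  if ("network" %in% config$stages) {
    need_labeled("network")
    d_star <- p$d_star_override %||% art$mean_d_star
    if (is.null(d_star))
      stop("network stage requires the distance stage or a d_star override")
    lab_map <- stats::setNames(
      vapply(map$polygons, `[[`, character(1), "label"),
      vapply(map$polygons, `[[`, character(1), "code_l3"))
    lab_map <- lab_map[!duplicated(names(lab_map))]
    art$networks <- list(); art$scores <- list()
    for (i in seq_len(length(years) - 1)) {
      key <- paste(years[i], years[i + 1], sep = "_")
      net <- build_transition_network(pos_year(years[i]),
                                      pos_year(years[i + 1]), d_star,
                                      year_pair = years[i:(i + 1)])
      art$networks[[key]] <- net
      art$scores[[key]] <- if (nrow(net$edges) > 0)
        score_nodes(net, labels = lab_map, seed = p$seed) else NULL
    }
  }

  # --- bivariate LISA -------------------------------------------------
  if ("lisa" %in% config$stages) {
    l <- need_labeled("lisa")
    source_code <- p$source_code
    if (is.null(source_code)) {
      if (is.null(art$scores) || is.null(art$scores[[1]]))
        stop("lisa stage requires a source_code or the network stage")
      source_code <- art$scores[[1]]$code[art$scores[[1]]$hub_rank == 1]
    }
    art$lisa <- list()
    for (i in seq_len(length(years) - 1)) {
      key <- paste(years[i], years[i + 1], sep = "_")
      art$lisa[[key]] <- lisa_field(
        l[l$year == years[i], , drop = FALSE],
        l[l$year == years[i + 1], , drop = FALSE],
        source_code, cell_size_m = p$lisa_cell_m,
        extent = map$extent, n_perm = p$n_perm, alpha = p$alpha,
        seed = p$seed)
    }
    art$lisa_source_code <- source_code
  }

  # --- write artifacts + manifest -------------------------------------
  if (!is.null(out_dir)) {
    fp <- function(...) file.path(out_dir, sprintf(...))
    write_tubes(tubes, fp("tubes.csv"))
    write_landuse(map, fp("landuse.geojson"))
    if (!is.null(art$foci))
      utils::write.csv(art$foci, fp("foci.csv"), row.names = FALSE)
    if (!is.null(art$labeled)) {
      write_tubes(art$labeled, fp("weighted_tubes.csv"))
      utils::write.csv(art$incidence, fp("incidence_by_year.csv"),
                       row.names = FALSE)
    }
    for (nm in names(art$surfaces)) {
      write_surface_csv(art$surfaces[[nm]], fp("surface_%s.csv", nm))
      write_ascii_grid(art$surfaces[[nm]], fp("surface_%s.asc", nm))
    }
    for (nm in names(art$curves))
      write_curve_csv(art$curves[[nm]], fp("curve_%s.csv", nm))
    if (!is.null(art$critical)) {
      cd <- data.frame(
        year_from = vapply(strsplit(names(art$critical), "_"),
                           function(s) as.integer(s[1]), integer(1)),
        year_to = vapply(strsplit(names(art$critical), "_"),
                         function(s) as.integer(s[2]), integer(1)),
        d_star_m = vapply(art$critical, `[[`, numeric(1), "d_star"))
      utils::write.csv(cd, fp("critical_distances.csv"), row.names = FALSE)
    }
    for (nm in names(art$networks)) {
      write_edges_csv(art$networks[[nm]], fp("network_%s.csv", nm))
      write_gexf(art$networks[[nm]], fp("network_%s.gexf", nm))
      if (!is.null(art$scores[[nm]]))
        utils::write.csv(art$scores[[nm]], fp("node_scores_%s.csv", nm),
                         row.names = FALSE)
    }
    for (nm in names(art$lisa))
      write_lisa(art$lisa[[nm]], fp("lisa_%s.csv", nm),
                 fp("lisa_%s.geojson", nm))
    manifest <- list(
      stages = config$stages,
      params = p[!vapply(p, is.null, logical(1))],
      seed = p$seed,
      simulation_seed = if (!is.null(config$simulation))
        config$simulation$seed else NULL,
      input_hashes = input_hashes,
      n_tubes = nrow(tubes),
      years = years)
    jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    art$manifest <- manifest
  }
  art
}
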