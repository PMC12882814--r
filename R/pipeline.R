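# Workflow driver: ties the stages into the three standard analyses
# (static niche quantification, neighborhood enrichment, track dynamics)
# with validated configuration, deterministic outputs and a provenance
# record.

pipeline_allowed <- list(
  niche = c("workflow", "seed", "scene", "min_area", "edge_len", "merge_dist",
            "min_total_area", "vessel_cutoff", "mode", "ratio_cutoff"),
  enrichment = c("workflow", "seed", "scene", "selected_type", "target_type",
                 "k_layers", "n_perm", "prune"),
  tracks = c("workflow", "seed", "tracks", "contact_threshold",
             "interaction_radius")
)

#' Run a complete analysis workflow
#'
#' Executes one of the three standard workflows on a synthetic scene /
#' track set described in the configuration, writes tidy CSV/JSON results
#' to `out_dir`, and records provenance (configuration echo and hash, seed,
#' package version). Identical configuration + seed produces byte-identical
#' output files.
#'
#' Configuration fields (YAML/JSON file or list):
#' * `workflow`: `"niche"`, `"enrichment"` or `"tracks"`.
#' * `seed`: integer used for every stochastic stage.
#' * `scene` (niche/enrichment): arguments for [scene_config()].
#' * `tracks` (tracks): arguments for [track_config()]; `planted_episodes`
#'   may be given as a list of `{dc_id, treg_id, start_frame, end_frame}`.
#' * thresholds: `min_area`, `edge_len`, `merge_dist`, `min_total_area`,
#'   `vessel_cutoff`, `mode`, `ratio_cutoff` (niche); `selected_type`,
#'   `target_type`, `k_layers`, `n_perm`, `prune` (enrichment);
#'   `contact_threshold`, `interaction_radius` (tracks).
#'
#' @param config list, or path to a YAML/JSON configuration file.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results and the paths
#'   written.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config) else
      jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config) || is.null(config$workflow)) {
    stop("config must name a `workflow`", call. = FALSE)
  }
  wf <- config$workflow
  if (!wf %in% names(pipeline_allowed)) {
    stop(sprintf("unknown workflow '%s' (niche | enrichment | tracks)", wf),
         call. = FALSE)
  }
  unknown <- setdiff(names(config), pipeline_allowed[[wf]])
  if (length(unknown) > 0L) {
    stop(sprintf("unknown parameter(s) for workflow '%s': %s", wf,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (is.null(config$seed)) stop("config must set `seed`", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  res <- switch(wf,
    niche = pipeline_niche(config, out_dir),
    enrichment = pipeline_enrichment(config, out_dir),
    tracks = pipeline_tracks(config, out_dir)
  )

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  prov <- list(
    workflow = wf,
    seed = config$seed,
    package = "dcniche",
    package_version = as.character(utils::packageVersion("dcniche")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = as.list(basename(res$paths))
  )
  prov_path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, digits = NA)
  res$paths <- c(res$paths, config = cfg_path, provenance = prov_path)
  invisible(res)
}

scene_from_config <- function(config) {
  args <- as.list(config$scene %||% list())
  args$seed <- config$seed
  generate_scene(do.call(scene_config, args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_niche <- function(config, out_dir) {
  scene <- scene_from_config(config)
  cfg <- association_config(vessel_cutoff = config$vessel_cutoff %||% 20,
                            mode = config$mode %||% "border")
  vessels <- classify_vessels(scene$surfaces$cd31, scene$surfaces$lyve1,
                              ratio_cutoff = config$ratio_cutoff %||% 1e-4)
  vessels <- ccl19_coverage(vessels, scene$surfaces$ccl19)
  det <- filter_detections(scene$detections, min_area = config$min_area %||% 5)
  assoc <- associate_cells(det, vessels, cfg)
  clusters <- delaunay_cluster(det,
                               edge_len = config$edge_len %||% 22.5,
                               merge_dist = config$merge_dist %||% 20,
                               min_total_area = config$min_total_area %||% 500)
  clusters <- associate_clusters(clusters, det, vessels, cfg)

  p1 <- file.path(out_dir, "dc_association.csv")
  utils::write.csv(assoc, p1, row.names = FALSE)
  cl_out <- as.data.frame(clusters[, setdiff(names(clusters), "members")])
  cl_out$members <- vapply(clusters$members, paste, character(1L), collapse = ";")
  p2 <- file.path(out_dir, "clusters.csv")
  utils::write.csv(cl_out, p2, row.names = FALSE)
  v_out <- as.data.frame(vessels[, setdiff(names(vessels), "boundary")])
  p3 <- file.path(out_dir, "vessels.csv")
  utils::write.csv(v_out, p3, row.names = FALSE)
  summary <- list(
    n_dc = nrow(det),
    association_fractions = as.list(prop.table(table(factor(assoc$label,
      levels = c("BV", "LV", "none"))))),
    n_clusters = nrow(clusters),
    cluster_association = as.list(table(factor(clusters$association,
      levels = c("BV", "LV", "none", "unassigned")))),
    bv_ccl19_area_fractions = as.list(attr(vessels, "bv_area_fractions"))
  )
  p4 <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, p4, auto_unbox = TRUE, digits = NA)
  list(scene = scene, vessels = vessels, association = assoc,
       clusters = clusters,
       paths = c(dc_association = p1, clusters = p2, vessels = p3,
                 summary = p4))
}

pipeline_enrichment <- function(config, out_dir) {
  scene <- scene_from_config(config)
  cells <- scene$cells
  g <- delaunay_graph(cells)
  g <- prune_percentile(g, config$prune %||% 99)
  sel_type <- config$selected_type %||% "DC"
  target <- config$target_type %||% "Treg"
  selected <- cells$cell_id[cells$cell_type == sel_type]
  enr <- permutation_enrichment(cells, g, selected, target,
                                k = config$k_layers %||% 5,
                                n_perm = config$n_perm %||% 1000,
                                seed = config$seed)
  Y <- nh_sum(cells, g, k = config$k_layers %||% 5)
  groups <- stats::setNames(ifelse(cells$cell_type == sel_type, sel_type, NA),
                            cells$cell_id)
  comp <- group_composition(Y, groups)

  p1 <- file.path(out_dir, "enrichment.json")
  jsonlite::write_json(list(
    selected_type = sel_type, target_type = target,
    n_selected = enr$n_selected,
    observed_density = enr$observed_density, baseline = enr$baseline,
    score = enr$score, p_value = enr$p_value, n_perm = enr$n_perm
  ), p1, auto_unbox = TRUE, digits = NA)
  p2 <- file.path(out_dir, "null_scores.json")
  jsonlite::write_json(enr$null_scores, p2, digits = NA)
  comp_df <- data.frame(group = rownames(comp)[row(comp)],
                        type = colnames(comp)[col(comp)],
                        ratio = as.vector(comp), stringsAsFactors = FALSE)
  p3 <- file.path(out_dir, "composition.csv")
  utils::write.csv(comp_df, p3, row.names = FALSE)
  list(scene = scene, enrichment = enr, composition = comp,
       paths = c(enrichment = p1, null_scores = p2, composition = p3))
}

pipeline_tracks <- function(config, out_dir) {
  args <- as.list(config$tracks %||% list())
  if (!is.null(args$planted_episodes) && !is.data.frame(args$planted_episodes)) {
    args$planted_episodes <- do.call(rbind, lapply(args$planted_episodes,
                                                   as.data.frame))
  }
  args$seed <- config$seed
  tracks <- generate_tracks(do.call(track_config, args))
  contacts <- detect_contacts(tracks,
                              threshold = config$contact_threshold %||% 5)
  cum <- cumulative_interactions(tracks,
                                 radius = config$interaction_radius %||% 20)
  speeds <- track_speed(tracks)

  p0 <- file.path(out_dir, "tracks.csv")
  write_tracks(tracks, p0)
  p1 <- file.path(out_dir, "contacts.csv")
  utils::write.csv(as.data.frame(contacts), p1, row.names = FALSE)
  p2 <- file.path(out_dir, "cumulative_interactions.csv")
  utils::write.csv(cum, p2, row.names = FALSE)
  p3 <- file.path(out_dir, "track_speeds.csv")
  utils::write.csv(speeds, p3, row.names = FALSE)
  list(tracks = tracks, contacts = contacts, cumulative = cum,
       speeds = speeds,
       paths = c(tracks = p0, contacts = p1, cumulative = p2, speeds = p3))
}
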