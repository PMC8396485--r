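# End-to-end orchestration: trajectory -> occurrence table + model
# histogram -> frequent models -> merged per-ligand model (+ RMSF, pairwise
# ligand RMSD, ring distances) -> final merged model across ligands ->
# validation screen. All artifacts are plain CSV/JSON and reproducible
# byte-for-byte for a fixed configuration and seed.

#' Pipeline configuration
#'
#' @param frames number of evenly distributed frames to analyze (the
#'   trajectory is downsampled to this count when longer; default 500).
#' @param window_frac fraction of analyzed frames, taken from the end of
#'   the run, used for pharmacophore statistics (default 0.2 -- the last
#'   20 ns of a 100 ns production run).
#' @param top_k_models number of most frequent models to merge (default 4).
#' @param merge_tol feature interpolation tolerance, A.
#' @param align_min_pairs,align_tol cross-ligand alignment criteria.
#' @param flags_spec essential/optional flag specification, see
#'   [apply_flags()].
#' @param rules a [geometric_rules()] object.
#' @param settings a [screen_settings()] object.
#' @param ef_fractions enrichment-factor fractions.
#' @param rmsd_samples frames used for the pairwise ligand RMSD matrix.
#' @return a `dynopharm_config` list.
#' @export
pipeline_config <- function(frames = 500, window_frac = 0.2,
                            top_k_models = 4, merge_tol = 1.5,
                            align_min_pairs = 3, align_tol = 1.5,
                            flags_spec = default_flags_spec(),
                            rules = geometric_rules(),
                            settings = screen_settings(),
                            ef_fractions = c(0.01, 0.05, 0.1),
                            rmsd_samples = NULL) {
  stopifnot(window_frac > 0, window_frac <= 1, top_k_models >= 1)
  structure(list(frames = frames, window_frac = window_frac,
                 top_k_models = top_k_models, merge_tol = merge_tol,
                 align_min_pairs = align_min_pairs, align_tol = align_tol,
                 flags_spec = flags_spec, rules = rules,
                 settings = settings, ef_fractions = ef_fractions,
                 rmsd_samples = rmsd_samples),
            class = "dynopharm_config")
}

#' Analyze one protein-ligand complex trajectory
#'
#' Runs the per-complex stage of the workflow: downsampling to the
#' configured frame count, alignment to the first frame, interaction
#' detection over the analysis window, occurrence table, unique-model
#' histogram, merging of the most frequent models into the per-ligand
#' model, per-residue RMSF, pairwise ligand RMSD and ring distances.
#'
#' @param traj a `dynopharm_traj`.
#' @param config a [pipeline_config()].
#' @param out_dir output directory for CSV/JSON artifacts, or `NULL` to
#'   skip writing.
#' @param ring_pairs optional residue pairs for [ring_distance_series()].
#' @return list with `occurrence`, `histogram`, `merged_model`, `rmsf`,
#'   `pairwise_rmsd`, `ring_distances`, `window` and (when written)
#'   `paths`.
#' @export
run_complex_analysis <- function(traj, config = pipeline_config(),
                                 out_dir = NULL, ring_pairs = NULL) {
  if (n_frames(traj) > config$frames) {
    traj <- downsample(traj, config$frames)
  }
  aligned <- align_to_first_frame(traj)
  window <- window_last_frac(aligned, config$window_frac)
  records <- trajectory_interactions(aligned, config$rules, window)
  occ <- occurrence_table(records = records)
  hist <- model_histogram(records = records)
  frequent <- select_frequent_models(records = records,
                                     k = config$top_k_models)
  merged <- merge_models(frequent, tol = config$merge_tol)
  merged$exclusion_volumes <- generate_exclusion_volumes(
    aligned, window = window, model = merged)
  rmsf <- rmsf_per_residue(aligned)
  prmsd <- pairwise_ligand_rmsd(aligned, n_samples = config$rmsd_samples)
  rings <- if (!is.null(ring_pairs)) {
    ring_distance_series(aligned, ring_pairs)
  }
  out <- list(occurrence = occ, histogram = hist, merged_model = merged,
              rmsf = rmsf, pairwise_rmsd = prmsd, ring_distances = rings,
              window = window)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      occurrence = file.path(out_dir, "occurrence_table.csv"),
      histogram = file.path(out_dir, "model_histogram.csv"),
      merged_model = file.path(out_dir, "merged_model.json"),
      rmsf = file.path(out_dir, "rmsf.csv"),
      pairwise_rmsd = file.path(out_dir, "pairwise_rmsd.csv"),
      ring_distances = file.path(out_dir, "ring_distances.csv"))
    readr::write_csv(occ, paths["occurrence"])
    readr::write_csv(hist, paths["histogram"])
    write_pharmacophore(merged, paths["merged_model"])
    readr::write_csv(rmsf, paths["rmsf"])
    readr::write_csv(as_tibble(as.data.frame(prmsd)),
                     paths["pairwise_rmsd"])
    if (!is.null(rings)) readr::write_csv(rings, paths["ring_distances"])
    else paths <- paths[names(paths) != "ring_distances"]
    out$paths <- paths
  }
  out
}

#' Build the final merged model from per-ligand models
#'
#' Thin orchestration over [build_final_model()]: aligns, merges,
#' devectorizes and flags, and reports excluded (un-alignable) models.
#'
#' @param merged_models named list of per-ligand models.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list with `final_model`, `excluded` (tibble of excluded ids and
#'   alignment diagnostics) and optional `paths`.
#' @export
run_final_model_build <- function(merged_models,
                                  config = pipeline_config(),
                                  out_dir = NULL) {
  final <- build_final_model(
    merged_models, flags_spec = config$flags_spec,
    min_pairs = config$align_min_pairs, align_tol = config$align_tol,
    merge_tol = config$merge_tol)
  excluded <- attr(final, "excluded")
  out <- list(final_model = final, excluded = excluded)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(final_model = file.path(out_dir, "final_model.json"),
               excluded = file.path(out_dir, "excluded_models.csv"))
    write_pharmacophore(final, paths["final_model"])
    readr::write_csv(excluded, paths["excluded"])
    out$paths <- paths
  }
  out
}

#' Validate a model by screening a labelled library
#'
#' @param model the final `dynopharm_model`.
#' @param library labelled library tibble (columns `id`, `molecule`,
#'   `label`).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list with `records` (screen records), `metrics`
#'   (a `dynopharm_enrichment`) and optional `paths`.
#' @export
run_validation <- function(model, library, config = pipeline_config(),
                           out_dir = NULL) {
  records <- screen_library(library, model, config$settings)
  metrics <- enrichment_metrics(records, fractions = config$ef_fractions)
  out <- list(records = records, metrics = metrics)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(records = file.path(out_dir, "screen_results.csv"),
               roc = file.path(out_dir, "roc_points.csv"),
               metrics = file.path(out_dir, "metrics.json"))
    readr::write_csv(records, paths["records"])
    readr::write_csv(metrics$roc, paths["roc"])
    jsonlite::write_json(
      list(auc = metrics$auc,
           n = metrics$n, n_actives = metrics$n_actives,
           tp = metrics$tp, fp = metrics$fp,
           ef = metrics$ef),
      paths["metrics"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$paths <- paths
  }
  out
}
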