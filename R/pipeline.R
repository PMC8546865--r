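## End-to-end orchestration over synthetic inputs: generate -> build library
## -> search -> calibrate -> filter -> aggregate, plus ground-truth
## evaluation of the final hit set. This is what the analysis drivers, the
## tests and the acceptance script run.

#' Build the identity-stratified model library from a reference catalog
#'
#' Clusters the curated records at `rep_cutoff` to pick representatives,
#' expands them against `database` across the identity grid, and builds one
#' profile model per (representative, non-empty bin).
#'
#' @param records curated catalog data frame (`id`, `sequence`,
#'   `plastic_type`, `compound_class`).
#' @param database expansion database (`id`, `sequence`); defaults to the
#'   records themselves.
#' @param rep_cutoff representative clustering identity cutoff (0.95).
#' @param expand_evalue_max expansion E-value cutoff (1e-10).
#' @param mode bin-assignment mode, see [expand_homologs()].
#' @param seed decoy seed for the expansion scorer.
#' @return list (`models`, `manifest`, `representatives`, `clusters`,
#'   `expansion`).
#' @export
build_library_from_catalog <- function(records, database = records,
                                       rep_cutoff = 0.95,
                                       expand_evalue_max = 1e-10,
                                       mode = "cumulative", seed = 1L) {
  clusters <- cluster_sequences(records, rep_cutoff)
  rep_ids <- vapply(clusters, `[[`, character(1), "representative_id")
  reps <- records[match(rep_ids, records$id), , drop = FALSE]
  expansion <- expand_homologs(reps, database,
                               evalue_max = expand_evalue_max,
                               mode = mode, seed = seed)
  lib <- build_model_library(reps, expansion, database)
  c(lib, list(representatives = reps, clusters = clusters,
              expansion = expansion))
}

#' Run the full synthetic-study pipeline
#'
#' Generates all inputs from `cfg`, builds the library, scores the
#' environmental and control catalogs, calibrates and filters, and
#' aggregates per-sample summaries.
#'
#' @param cfg a [generator_config()].
#' @param filter_cfg a [filter_config()].
#' @param n_decoys decoy scores per model for E-value calibration.
#' @param evalue_report_max raw-hit report threshold (loose, so calibration
#'   sees control scores).
#' @return list with every stage's output: `cfg`, `families`, `catalogs`,
#'   `metadata`, `surveys`, `library`, `env_hits`, `control_hits`,
#'   `calibration`, `final_hits`, `sample_summaries`, `evaluation`.
#' @export
run_pipeline <- function(cfg = generator_config(),
                         filter_cfg = filter_config(),
                         n_decoys = 10000L, evalue_report_max = 10) {
  families <- generate_enzyme_families(cfg)
  catalogs <- generate_catalogs(cfg, families)
  metadata <- generate_geo_metadata(cfg)
  surveys <- generate_pollution_surveys(cfg, metadata)

  library <- build_library_from_catalog(families$records,
                                        seed = gen_seed(cfg, 6L))

  env_raw <- score_catalog(library, catalogs$catalog,
                           evalue_report_max = evalue_report_max,
                           origin = "environmental", n_decoys = n_decoys,
                           seed = gen_seed(cfg, 7L))
  ctl_raw <- score_catalog(library, catalogs$control,
                           evalue_report_max = evalue_report_max,
                           origin = "control", n_decoys = n_decoys,
                           seed = gen_seed(cfg, 8L))
  env_hits <- deduplicate_hits(env_raw)
  ctl_hits <- deduplicate_hits(ctl_raw)

  calibration <- calibrate_library(env_hits, ctl_hits, library$manifest,
                                   filter_cfg)
  final_hits <- filter_hits(env_hits, calibration, filter_cfg)
  sample_summaries <- summarize_samples(final_hits, library$manifest)
  evaluation <- evaluate_against_truth(final_hits, catalogs$truth,
                                       calibration, library,
                                       families$records)
  list(cfg = cfg, families = families, catalogs = catalogs,
       metadata = metadata, surveys = surveys, library = library,
       env_hits = env_hits, control_hits = ctl_hits,
       calibration = calibration, final_hits = final_hits,
       sample_summaries = sample_summaries, evaluation = evaluation)
}

#' Evaluate final hits against generator ground truth
#'
#' @param final_hits filtered hit table.
#' @param truth generator truth table.
#' @param calibration calibration report.
#' @param library model library.
#' @param records reference catalog records (id -> family).
#' @return list: `precision` (fraction of final hits that are planted
#'   homologues), `recall` (fraction of planted genes recovered by a model
#'   of their source family), `family_retention` (fraction of families with
#'   at least one retained model), `retained_fraction` (retained models /
#'   library size).
#' @export
evaluate_against_truth <- function(final_hits, truth, calibration, library,
                                   records) {
  is_hom <- stats::setNames(truth$is_homolog, truth$gene_id)
  src_fam <- stats::setNames(truth$source_family, truth$gene_id)
  fam_of_rep <- stats::setNames(records$family, records$id)
  hit_fam <- unname(fam_of_rep[library$manifest$representative_id[
    match(final_hits$model_id, library$manifest$model_id)]])
  precision <- if (nrow(final_hits)) mean(is_hom[final_hits$gene_id]) else NA_real_
  planted <- truth$gene_id[truth$is_homolog]
  recovered <- final_hits$gene_id[hit_fam == unname(src_fam[final_hits$gene_id])]
  recall <- if (length(planted)) mean(planted %in% recovered) else NA_real_
  ret_models <- calibration$model_id[calibration$retained]
  ret_fams <- unique(unname(fam_of_rep[library$manifest$representative_id[
    match(ret_models, library$manifest$model_id)]]))
  families <- unique(records$family)
  list(precision = precision, recall = recall,
       family_retention = mean(families %in% ret_fams),
       retained_fraction = length(ret_models) / nrow(library$manifest))
}

#' Per-sample final hit counts as a named vector
#'
#' Samples generated by the study design but absent from the hit table get
#' zero counts when `all_samples` is supplied.
#'
#' @param sample_summaries output of [summarize_samples()].
#' @param all_samples optional character vector of every sample id.
#' @return named numeric vector sample_id -> n_hits.
#' @export
hit_count_vector <- function(sample_summaries, all_samples = NULL) {
  v <- stats::setNames(sample_summaries$n_hits, sample_summaries$sample_id)
  if (!is.null(all_samples)) {
    out <- stats::setNames(numeric(length(all_samples)), all_samples)
    out[names(v)] <- v
    v <- out
  }
  v
}
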