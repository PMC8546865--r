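## Reporting units: per-sample and per-dataset hit summaries (the study's
## overview-table shape), polymer/additive partition, EC annotation
## coverage, and per-genome-bin plastic profiles.

#' Per-sample summaries of filtered hits
#'
#' @param final_hits filtered hit table.
#' @param manifest library manifest (model_id -> plastic_type,
#'   compound_class).
#' @param sample_datasets optional named character vector
#'   sample_id -> dataset label.
#' @return data frame (`sample_id`, `n_hits`, `n_plastic_types`,
#'   `n_polymer_hits`, `n_additive_hits`, `dataset`), one row per sample
#'   present in the hit table.
#' @export
summarize_samples <- function(final_hits, manifest, sample_datasets = NULL) {
  if (nrow(final_hits) == 0L) {
    return(data.frame(sample_id = character(0), n_hits = integer(0),
                      n_plastic_types = integer(0), n_polymer_hits = integer(0),
                      n_additive_hits = integer(0), dataset = character(0),
                      stringsAsFactors = FALSE))
  }
  idx <- match(final_hits$model_id, manifest$model_id)
  if (anyNA(idx)) stop("summarize_samples: hit with unknown model")
  if (!is.null(sample_datasets) &&
      any(!final_hits$sample_id %in% names(sample_datasets)))
    stop("summarize_samples: hit with unknown sample")
  h <- data.frame(sample_id = final_hits$sample_id,
                  plastic_type = manifest$plastic_type[idx],
                  compound_class = manifest$compound_class[idx],
                  stringsAsFactors = FALSE)
  sp <- split(h, h$sample_id)
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(sample_id = g$sample_id[1],
               n_hits = nrow(g),
               n_plastic_types = length(unique(g$plastic_type)),
               n_polymer_hits = sum(g$compound_class == "polymer"),
               n_additive_hits = sum(g$compound_class == "additive"),
               stringsAsFactors = FALSE)
  }))
  out$dataset <- if (is.null(sample_datasets)) NA_character_
                 else unname(sample_datasets[out$sample_id])
  rownames(out) <- NULL
  out
}

#' Derived statistics for a per-dataset count table
#'
#' Adds `hits_per_gene` (3 significant figures), a `total` row (column sums)
#' and a `mean` row (arithmetic mean of the dataset rows, rounded to
#' integers for counts). The mean row's `hits_per_gene` is recomputed as
#' total hits / total genes, matching how the study's overview table prints
#' that column.
#'
#' @param df data frame with columns `dataset`, `n_genes`, `n_samples`,
#'   `n_models_hit`, `n_hits`, `n_plastic_types`, `n_polymer_hits`,
#'   `n_additive_hits` (one row per dataset).
#' @param n_plastic_types_total distinct plastic types over all datasets for
#'   the total row (defaults to the max per-dataset value).
#' @param n_models_total distinct models hit over all datasets for the total
#'   row (defaults to `NA`; pass the union count when known).
#' @return data frame with the dataset rows plus `mean` and `total` rows.
#' @export
dataset_summary <- function(df, n_plastic_types_total = max(df$n_plastic_types),
                            n_models_total = NA_integer_) {
  stopifnot(all(df$n_genes > 0))
  cols <- c("n_genes", "n_samples", "n_models_hit", "n_hits",
            "n_plastic_types", "n_polymer_hits", "n_additive_hits")
  df$hits_per_gene <- signif(df$n_hits / df$n_genes, 3)
  if ("group" %in% names(df)) df$group <- as.character(df$group)
  mean_row <- df[1, , drop = FALSE]
  mean_row$dataset <- "mean"
  if ("group" %in% names(df)) mean_row$group <- NA_character_
  for (cl in cols) mean_row[[cl]] <- round(mean(df[[cl]]))
  mean_row$hits_per_gene <- signif(sum(df$n_hits) / sum(df$n_genes), 3)
  total_row <- df[1, , drop = FALSE]
  total_row$dataset <- "total"
  if ("group" %in% names(df)) total_row$group <- NA_character_
  for (cl in cols) total_row[[cl]] <- sum(df[[cl]])
  total_row$n_plastic_types <- n_plastic_types_total
  total_row$n_models_hit <- n_models_total
  total_row$hits_per_gene <- NA_real_
  out <- rbind(df, mean_row, total_row)
  rownames(out) <- NULL
  out
}

#' Aggregate sample summaries into per-dataset summaries
#'
#' @param samples output of [summarize_samples()] with a `dataset` column.
#' @param gene_counts data frame (`dataset`, `n_genes`).
#' @param final_hits,manifest optional, used to count distinct models and
#'   plastic types per dataset and over all datasets.
#' @return [dataset_summary()] table.
#' @export
summarize_datasets <- function(samples, gene_counts, final_hits = NULL,
                               manifest = NULL) {
  stopifnot(all(gene_counts$n_genes > 0))
  sp <- split(samples, samples$dataset)
  per_ds_models <- NULL
  if (!is.null(final_hits) && !is.null(manifest)) {
    ds_of <- stats::setNames(samples$dataset, samples$sample_id)
    hd <- data.frame(dataset = unname(ds_of[final_hits$sample_id]),
                     model_id = final_hits$model_id,
                     plastic_type = manifest$plastic_type[
                       match(final_hits$model_id, manifest$model_id)],
                     stringsAsFactors = FALSE)
    per_ds_models <- split(hd, hd$dataset)
  }
  df <- do.call(rbind, lapply(names(sp), function(ds) {
    g <- sp[[ds]]
    nm <- if (!is.null(per_ds_models) && ds %in% names(per_ds_models)) {
      length(unique(per_ds_models[[ds]]$model_id))
    } else NA_integer_
    npt <- if (!is.null(per_ds_models) && ds %in% names(per_ds_models)) {
      length(unique(per_ds_models[[ds]]$plastic_type))
    } else max(g$n_plastic_types)
    data.frame(dataset = ds,
               n_genes = gene_counts$n_genes[match(ds, gene_counts$dataset)],
               n_samples = nrow(g), n_models_hit = nm, n_hits = sum(g$n_hits),
               n_plastic_types = npt,
               n_polymer_hits = sum(g$n_polymer_hits),
               n_additive_hits = sum(g$n_additive_hits),
               stringsAsFactors = FALSE)
  }))
  npt_tot <- if (!is.null(per_ds_models)) {
    length(unique(unlist(lapply(per_ds_models, `[[`, "plastic_type"))))
  } else max(df$n_plastic_types)
  nm_tot <- if (!is.null(per_ds_models)) {
    length(unique(unlist(lapply(per_ds_models, `[[`, "model_id"))))
  } else NA_integer_
  dataset_summary(df, n_plastic_types_total = npt_tot,
                  n_models_total = nm_tot)
}

#' Additive (or polymer) share of hits over a dataset group, in percent
#'
#' @param df per-dataset table (dataset rows of [dataset_summary()]).
#' @param datasets which datasets to pool.
#' @param class `"additive"` or `"polymer"`.
#' @return integer-rounded percentage.
#' @export
compound_share_pct <- function(df, datasets = df$dataset,
                               class = c("additive", "polymer")) {
  class <- match.arg(class)
  g <- df[df$dataset %in% datasets, , drop = FALSE]
  col <- if (class == "additive") "n_additive_hits" else "n_polymer_hits"
  round(100 * sum(g[[col]]) / sum(g$n_hits))
}

#' Retained-model fraction in percent
#'
#' @param n_retained retained (unique) model count.
#' @param n_initial initial library size.
#' @return integer-rounded percentage.
#' @export
retained_fraction_pct <- function(n_retained, n_initial) {
  round(100 * n_retained / n_initial)
}

#' EC annotation coverage of the final hits
#'
#' @param final_hits filtered hit table.
#' @param annotations data frame (`gene_id`, `ec`); EC strings like
#'   `"3.1.1.-"`. Genes absent from the table count as unannotated;
#'   malformed EC strings are skipped and counted.
#' @param manifest library manifest, for the polymer/additive split.
#' @return list: `fraction_annotated`, `by_class` (named fractions),
#'   `ec_class_histogram` (table over the top EC level), `n_malformed`.
#' @export
annotation_coverage <- function(final_hits, annotations, manifest) {
  ok_ec <- grepl("^[0-9]+(\\.([0-9]+|-)){0,3}$", annotations$ec)
  n_malformed <- sum(!ok_ec)
  ann <- annotations[ok_ec, , drop = FALSE]
  ec_of <- stats::setNames(ann$ec, ann$gene_id)
  annotated <- final_hits$gene_id %in% names(ec_of)
  cls <- manifest$compound_class[match(final_hits$model_id, manifest$model_id)]
  by_class <- vapply(c(polymer = "polymer", additive = "additive"),
                     function(cc) {
                       sel <- cls == cc
                       if (!any(sel)) return(NA_real_)
                       mean(annotated[sel])
                     }, numeric(1))
  top <- sub("\\..*$", "", unname(ec_of[final_hits$gene_id[annotated]]))
  list(fraction_annotated = if (nrow(final_hits)) mean(annotated) else 0,
       by_class = by_class,
       ec_class_histogram = table(top),
       n_malformed = n_malformed)
}

#' Per-genome-bin plastic profiles
#'
#' Hits on unbinned genes are excluded from the profiles but retained in the
#' totals; the histogram counts distinct plastic types per bin.
#'
#' @param final_hits filtered hit table.
#' @param gene_bins data frame (`gene_id`, `bin_id`); may be partial.
#' @param bin_taxonomy data frame (`bin_id`, `taxon_path`); may be partial.
#' @param manifest library manifest.
#' @return list: `profiles` (data frame bin_id, taxon_path, n_hits,
#'   plastic_types), `types_per_bin` (table), `n_hits_total`,
#'   `n_hits_binned`.
#' @export
genome_bin_profiles <- function(final_hits, gene_bins, bin_taxonomy,
                                manifest) {
  bin_of <- stats::setNames(gene_bins$bin_id, gene_bins$gene_id)
  tax_of <- stats::setNames(bin_taxonomy$taxon_path, bin_taxonomy$bin_id)
  binned <- final_hits$gene_id %in% names(bin_of)
  h <- final_hits[binned, , drop = FALSE]
  if (nrow(h) == 0L) {
    return(list(profiles = data.frame(bin_id = character(0),
                                      taxon_path = character(0),
                                      n_hits = integer(0),
                                      plastic_types = character(0),
                                      stringsAsFactors = FALSE),
                types_per_bin = table(integer(0)),
                n_hits_total = nrow(final_hits), n_hits_binned = 0L))
  }
  h$bin_id <- unname(bin_of[h$gene_id])
  h$plastic_type <- manifest$plastic_type[match(h$model_id, manifest$model_id)]
  sp <- split(h, h$bin_id)
  profiles <- do.call(rbind, lapply(sp, function(g) {
    types <- sort(unique(g$plastic_type))
    data.frame(bin_id = g$bin_id[1],
               taxon_path = if (g$bin_id[1] %in% names(tax_of))
                 unname(tax_of[g$bin_id[1]]) else NA_character_,
               n_hits = nrow(g),
               plastic_types = paste(types, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(profiles) <- NULL
  n_types <- vapply(strsplit(profiles$plastic_types, ","), length, integer(1))
  list(profiles = profiles, types_per_bin = table(n_types),
       n_hits_total = nrow(final_hits), n_hits_binned = nrow(h))
}

#' Load the packaged study overview-table fixture
#'
#' The per-dataset counts printed in the study's overview table (genes,
#' samples, models hit, hits, plastic types, polymer/additive split for the
#' three soil datasets and the ocean dataset), with the initial and retained
#' model-library sizes in the provenance header.
#'
#' @return data frame with a `"provenance"` attribute carrying
#'   `n_initial_models` and `n_retained_models`.
#' @export
study_overview_fixture <- function() {
  path <- system.file("extdata", "study_dataset_counts.tsv",
                      package = "plasticmine", mustWork = TRUE)
  read_tsv_prov(path)
}
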