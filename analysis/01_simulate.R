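#!/usr/bin/env Rscript
## Stage 1 — generate the synthetic study inputs.
##
## Emulates the study's raw materials with controllable ground truth: a
## curated catalog of plastic-degrading enzyme families, per-sample
## environmental gene catalogs with planted homologues whose abundance
## tracks a latent pollution field, a gut-like control catalog of
## composition-matched decoys, geolocated sample metadata, and four
## pollution surveys on incompatible measurement scales.

suppressMessages(library(plasticmine))

seed <- 1L
cfg <- generator_config(seed = seed)
dir.create("results", showWarnings = FALSE)

families <- generate_enzyme_families(cfg)
catalogs <- generate_catalogs(cfg, families)
metadata <- generate_geo_metadata(cfg)
surveys <- generate_pollution_surveys(cfg, metadata)

write_fasta(setNames(families$records$sequence, families$records$id),
            "results/reference_catalog.fasta")
write_tsv_prov(families$records[, c("id", "plastic_type", "compound_class",
                                    "family")],
               "results/reference_labels.tsv", seed)
write_fasta(setNames(catalogs$catalog$sequence, catalogs$catalog$gene_id),
            "results/environmental_catalog.fasta")
write_fasta(setNames(catalogs$control$sequence, catalogs$control$gene_id),
            "results/control_catalog.fasta")
write_tsv_prov(catalogs$truth, "results/truth_table.tsv", seed)
write_tsv_prov(metadata, "results/sample_metadata.tsv", seed)
write_tsv_prov(do.call(rbind, surveys), "results/pollution_surveys.tsv", seed)
saveRDS(list(cfg = cfg, families = families, catalogs = catalogs,
             metadata = metadata, surveys = surveys),
        "results/01_simulated.rds")

cat(sprintf("Generated %d reference enzymes in %d families,\n",
            nrow(families$records), cfg$n_families))
cat(sprintf("%d environmental genes across %d samples (%d planted homologues),\n",
            nrow(catalogs$catalog), cfg$n_samples,
            sum(catalogs$truth$is_homolog)))
cat(sprintf("a %d-gene control catalog, and %d pollution surveys.\n",
            nrow(catalogs$control), cfg$n_surveys))
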