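test_that("configuration validation rejects out-of-range parameters", {
  expect_error(generator_config(within_family_divergence = 1), "divergence")
  expect_error(generator_config(target_rho = 1.5), "target_rho")
  expect_error(generator_config(n_families = 0), "count")
  expect_error(generator_config(planted_fraction = 1.2), "planted_fraction")
  expect_error(generator_config(survey_scale_factors = c(1, -1)), "positive")
})

test_that("families are deterministic under seed and exact at zero divergence", {
  cfg0 <- tiny_cfg(within_family_divergence = 0)
  fam <- generate_enzyme_families(cfg0)
  for (f in unique(fam$records$family)) {
    members <- fam$records$sequence[fam$records$family == f]
    expect_true(all(members == fam$ancestors[[f]]))
  }
  f1 <- generate_enzyme_families(tiny_cfg())
  f2 <- generate_enzyme_families(tiny_cfg())
  expect_identical(f1, f2)
  ## FASTA serialization is byte-identical too
  p1 <- tempfile(fileext = ".fasta"); p2 <- tempfile(fileext = ".fasta")
  write_fasta(setNames(f1$records$sequence, f1$records$id), p1)
  write_fasta(setNames(f2$records$sequence, f2$records$id), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("member identity to the ancestor matches the substitution rate", {
  cfg <- generator_config(seed = 1, n_families = 10, family_size = 4,
                          seq_length = 200, within_family_divergence = 0.2,
                          n_samples = 4, genes_per_sample = 5,
                          control_genes = 20)
  fam <- generate_enzyme_families(cfg)
  ident <- mapply(function(s, f) {
    mean(strsplit(s, "")[[1]] == strsplit(fam$ancestors[[f]], "")[[1]])
  }, fam$records$sequence, fam$records$family)
  ## binomial expectation 0.8, 3-sigma band +/-0.06 on the family mean
  expect_lt(abs(mean(ident) - 0.8), 0.06)
})

test_that("catalogs respect planted_fraction extremes and truth covers all genes", {
  cfg0 <- tiny_cfg(planted_fraction = 0)
  fam <- generate_enzyme_families(cfg0)
  cats <- generate_catalogs(cfg0, fam)
  expect_equal(sum(cats$truth$is_homolog), 0)

  cfg1 <- tiny_cfg(planted_fraction = 1, genes_per_sample = 10)
  cats1 <- generate_catalogs(cfg1, generate_enzyme_families(cfg1))
  per_sample <- tapply(cats1$truth$is_homolog[
    grepl("^S", cats1$truth$gene_id)],
    sub("_g.*", "", cats1$truth$gene_id[grepl("^S", cats1$truth$gene_id)]),
    sum)
  expect_true(all(per_sample == 10))

  ## truth ids are exactly the union of catalog + control ids, no duplicates
  cats <- generate_catalogs(tiny_cfg(), generate_enzyme_families(tiny_cfg()))
  all_ids <- c(cats$catalog$gene_id, cats$control$gene_id)
  expect_setequal(cats$truth$gene_id, all_ids)
  expect_false(anyDuplicated(cats$truth$gene_id) > 0)
})

test_that("control near-decoys are less similar to the families than planted homologues", {
  cfg <- tiny_cfg(seed = 3)
  fam <- generate_enzyme_families(cfg)
  cats <- generate_catalogs(cfg, fam)
  planted <- cats$catalog$sequence[cats$truth$is_homolog[
    match(cats$catalog$gene_id, cats$truth$gene_id)]]
  decoys <- cats$control$sequence[1:10]     # first half are shuffles
  best_decoy <- max(vapply(decoys, function(d) {
    max(vapply(fam$records$sequence, function(s) pairwise_identity(d, s),
               numeric(1)))
  }, numeric(1)))
  planted_med <- median(vapply(planted[1:10], function(p) {
    max(vapply(fam$records$sequence, function(s) pairwise_identity(p, s),
               numeric(1)))
  }, numeric(1)))
  expect_lt(best_decoy, planted_med)
})

test_that("geo metadata is in range with ordered depth layers and a seeded field", {
  cfg <- tiny_cfg(n_samples = 40)
  md <- generate_geo_metadata(cfg)
  expect_equal(nrow(md), 40)
  expect_true(all(abs(md$lat) <= 90), all(abs(md$lon) <= 180))
  means <- tapply(md$depth_m, md$layer, mean)
  expect_true(means[["SRF"]] < means[["DCM"]], means[["DCM"]] < means[["MES"]])
  expect_identical(md$pollution_field, latent_field(cfg))
  expect_identical(generate_geo_metadata(cfg), md)
})

test_that("planted counts track the pollution field at the target Spearman", {
  ## monotone coupling at target_rho = 1 (marginal chosen tie-free)
  cfg1 <- generator_config(seed = 5, n_samples = 8, genes_per_sample = 5000,
                           target_rho = 1, n_families = 2, family_size = 2,
                           seq_length = 50, control_genes = 10)
  f <- latent_field(cfg1)
  ct <- sample_planted_counts(cfg1, f)
  expect_equal(cor(f, ct, method = "spearman"), 1)
  ## null coupling stays near zero at n = 60
  cfg0 <- generator_config(seed = 1, n_samples = 60, target_rho = 0)
  expect_lt(abs(cor(latent_field(cfg0), sample_planted_counts(cfg0),
                    method = "spearman")), 0.3)
  ## convergence to target at n = 500
  cfg5 <- generator_config(seed = 1, n_samples = 500)
  expect_lt(abs(cor(latent_field(cfg5), sample_planted_counts(cfg5),
                    method = "spearman") - 0.5), 0.05)
})

test_that("pollution surveys rescale the same field monotonically", {
  cfg <- generator_config(seed = 2, n_samples = 24, n_surveys = 2,
                          survey_scale_factors = c(1, 1000),
                          survey_noise_sd = 0, n_families = 2,
                          family_size = 2, seq_length = 50,
                          control_genes = 10)
  md <- generate_geo_metadata(cfg)
  sv <- generate_pollution_surveys(cfg, md)
  ## scale factors differ by 1000x but both are monotone in the field
  idx1 <- ((seq_len(24) - 1) %% 2) + 1 == 1
  expect_equal(order(sv[[1]]$value), order(md$pollution_field[idx1]))
  pooled <- pool_surveys(sv)
  ## after pooling, z-scores of each survey preserve the field's rank order
  for (s in c("SURV1", "SURV2")) {
    sub <- pooled[pooled$survey_id == s, ]
    expect_equal(order(sub$pooled_z), order(sub$value))
  }
  expect_identical(generate_pollution_surveys(cfg, md), sv)
})

test_that("provenance headers round-trip through the TSV writer", {
  df <- data.frame(a = 1:3, b = c("x", "y", "z"))
  p <- tempfile(fileext = ".tsv")
  write_tsv_prov(df, p, seed = 99, extra = c(stage = "unit"))
  back <- read_tsv_prov(p)
  expect_equal(back$a, df$a)
  prov <- attr(back, "provenance")
  expect_equal(prov[["seed"]], "99")
  expect_equal(prov[["stage"]], "unit")
})
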