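## Synthetic-data generator: emulates the study's inputs (curated enzyme
## catalog, environmental + control gene catalogs, geolocated sample
## metadata, multi-survey pollution measurements) with controllable ground
## truth, so the whole pipeline can be exercised and tested offline.

## plastic / additive labels used to annotate synthetic families; the field's
## usual polymer abbreviations plus the phthalate-based additive group
PLASTIC_TYPES <- data.frame(
  plastic_type = c("PET", "PU", "PHB", "PLA", "PEG", "PBAT", "PE", "PBS",
                   "PVA", "PHO", "phthalate", "PA", "DBP", "TP"),
  compound_class = c(rep("polymer", 10), rep("additive", 4)),
  stringsAsFactors = FALSE
)

#' Configuration for the synthetic-data generator
#'
#' Defaults are the study conditions used throughout the package's tests and
#' analyses: 20 enzyme families of 4 members at 0.2 substitutions/site, 40
#' geolocated samples of 100 genes with 30% planted homologues on average, a
#' 2,000-gene control catalog, and 4 pollution surveys on scales spanning
#' three orders of magnitude, coupled to the planted counts at Spearman 0.5.
#'
#' @param seed integer seed; recorded in every output's provenance header.
#' @param n_families number of enzyme families.
#' @param family_size members per family.
#' @param seq_length sequence length, residues.
#' @param within_family_divergence substitutions per site in `[0, 1)` applied
#'   independently to each member relative to the family ancestor.
#' @param n_samples number of geolocated samples.
#' @param genes_per_sample genes in each sample's catalog.
#' @param planted_fraction mean fraction of a sample's genes that are true
#'   homologues; realized per-sample counts vary with the pollution field.
#' @param control_genes size of the negative-control catalog.
#' @param target_rho population Spearman correlation in `[-1, 1]` between the
#'   latent pollution field and planted per-sample homologue counts.
#' @param n_surveys number of pollution surveys.
#' @param survey_scale_factors positive multiplier per survey (recycled),
#'   emulating surveys reporting on different measurement scales.
#' @param survey_noise_sd standard deviation of the log-scale measurement
#'   noise added to the latent field by each survey.
#' @param coord_jitter_deg half-width (degrees) of the uniform jitter applied
#'   to survey point coordinates around the sample they measure near.
#' @return object of class `generator_config` (a validated list).
#' @export
generator_config <- function(seed = 1L,
                             n_families = 20L,
                             family_size = 4L,
                             seq_length = 200L,
                             within_family_divergence = 0.2,
                             n_samples = 40L,
                             genes_per_sample = 100L,
                             planted_fraction = 0.3,
                             control_genes = 2000L,
                             target_rho = 0.5,
                             n_surveys = 4L,
                             survey_scale_factors = c(1, 10, 100, 1000),
                             survey_noise_sd = 0.1,
                             coord_jitter_deg = 0.5) {
  cfg <- list(seed = as.integer(seed), n_families = as.integer(n_families),
              family_size = as.integer(family_size),
              seq_length = as.integer(seq_length),
              within_family_divergence = within_family_divergence,
              n_samples = as.integer(n_samples),
              genes_per_sample = as.integer(genes_per_sample),
              planted_fraction = planted_fraction,
              control_genes = as.integer(control_genes),
              target_rho = target_rho, n_surveys = as.integer(n_surveys),
              survey_scale_factors = rep_len(survey_scale_factors,
                                             as.integer(n_surveys)),
              survey_noise_sd = survey_noise_sd,
              coord_jitter_deg = coord_jitter_deg)
  counts <- c("n_families", "family_size", "seq_length", "n_samples",
              "genes_per_sample", "control_genes", "n_surveys")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop("generator_config: '", nm, "' must be a count >= 1")
  }
  if (cfg$within_family_divergence < 0 || cfg$within_family_divergence >= 1)
    stop("generator_config: within_family_divergence must be in [0, 1)")
  if (cfg$planted_fraction < 0 || cfg$planted_fraction > 1)
    stop("generator_config: planted_fraction must be in [0, 1]")
  if (abs(cfg$target_rho) > 1)
    stop("generator_config: |target_rho| must be <= 1")
  if (any(cfg$survey_scale_factors <= 0))
    stop("generator_config: survey_scale_factors must be positive")
  if (cfg$seed < 0 || cfg$seed > .Machine$integer.max - 10L)
    stop("generator_config: seed out of range")
  class(cfg) <- "generator_config"
  cfg
}

## sub-stream seeds so each generate_* call is independently reproducible
gen_seed <- function(cfg, k) cfg$seed + k

random_aa <- function(n, L) {
  vapply(seq_len(n),
         function(i) paste(sample(AA20, L, replace = TRUE), collapse = ""),
         character(1))
}

## substitute each position independently with prob `rate`, drawing the new
## residue uniformly from the 19 others (so expected identity = 1 - rate)
mutate_sequence <- function(s, rate) {
  x <- aa_to_int(s)
  hit <- runif(length(x)) < rate
  if (any(hit)) {
    shift <- sample.int(19L, sum(hit), replace = TRUE)
    x[hit] <- ((x[hit] - 1L + shift) %% 20L) + 1L
  }
  paste(AA20[x], collapse = "")
}

shuffle_sequence <- function(s) {
  paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Latent pollution field underlying a synthetic study
#'
#' One standard-normal value per sample, drawn from a dedicated sub-stream of
#' the configuration seed so that catalogs, metadata and surveys all see the
#' same field.
#'
#' @param cfg a [generator_config()].
#' @return numeric vector of length `cfg$n_samples`.
#' @export
latent_field <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(gen_seed(cfg, 3L))
  rnorm(cfg$n_samples)
}

#' Planted homologue counts coupled to the pollution field
#'
#' Counts are drawn through a Gaussian copula: a latent normal correlated
#' with the field at Pearson `2*sin(pi*target_rho/6)` (the bivariate-normal
#' inverse of Spearman's rho) is pushed through the binomial
#' `(genes_per_sample, planted_fraction)` quantile function. This yields
#' integer counts with the configured mean whose population Spearman
#' correlation with the field equals `target_rho` (up to the small tie-induced
#' attenuation of the discrete marginal).
#'
#' @param cfg a [generator_config()].
#' @param field latent field values, default [latent_field()].
#' @return integer vector of planted counts per sample.
#' @export
sample_planted_counts <- function(cfg, field = latent_field(cfg)) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(gen_seed(cfg, 2L))
  rho_p <- 2 * sin(pi * cfg$target_rho / 6)
  eps <- rnorm(length(field))
  y <- rho_p * field + sqrt(1 - rho_p^2) * eps
  qbinom(pnorm(y), cfg$genes_per_sample, cfg$planted_fraction)
}

#' Generate synthetic enzyme families
#'
#' Each family has one random ancestral sequence over the 20-letter alphabet;
#' members are derived by i.i.d. substitution at the configured divergence.
#' Families carry plastic-type and polymer/additive class labels.
#'
#' @param cfg a [generator_config()].
#' @return list with `records` (data frame: id, sequence, plastic_type,
#'   compound_class, family — the curated reference catalog) and `ancestors`
#'   (named character vector of ancestral sequences per family).
#' @export
generate_enzyme_families <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$within_family_divergence >= 1)
    stop("within_family_divergence must be < 1")
  set.seed(gen_seed(cfg, 1L))
  fam_ids <- sprintf("F%02d", seq_len(cfg$n_families))
  anc <- random_aa(cfg$n_families, cfg$seq_length)
  names(anc) <- fam_ids
  types <- PLASTIC_TYPES[((seq_len(cfg$n_families) - 1L) %%
                            nrow(PLASTIC_TYPES)) + 1L, ]
  recs <- do.call(rbind, lapply(seq_len(cfg$n_families), function(f) {
    members <- vapply(seq_len(cfg$family_size), function(m) {
      mutate_sequence(anc[[f]], cfg$within_family_divergence)
    }, character(1))
    data.frame(id = sprintf("%s_M%d", fam_ids[f], seq_len(cfg$family_size)),
               sequence = members,
               plastic_type = types$plastic_type[f],
               compound_class = types$compound_class[f],
               family = fam_ids[f], stringsAsFactors = FALSE)
  }))
  rownames(recs) <- NULL
  list(records = recs, ancestors = anc)
}

#' Generate environmental and control gene catalogs with ground truth
#'
#' Each sample's catalog holds planted homologues (drawn from family
#' ancestors at the configured divergence, counts coupled to the latent
#' pollution field; see [sample_planted_counts()]) plus i.i.d. uniform
#' background genes. The control catalog holds background genes and
#' "near-decoys": residue shuffles of family members, composition-matched
#' negatives that stress the calibration filter the way shared-ancestry gut
#' homologues do against real models.
#'
#' @param cfg a [generator_config()].
#' @param families output of [generate_enzyme_families()].
#' @return list with `catalog` (data frame: gene_id, sample_id, sequence),
#'   `control` (data frame: gene_id, sequence), `truth` (data frame: gene_id,
#'   is_homolog, source_family covering every generated gene), and
#'   `planted_counts` (integer per sample).
#' @export
generate_catalogs <- function(cfg, families) {
  stopifnot(inherits(cfg, "generator_config"))
  if (nrow(families$records) == 0L) stop("families must be non-empty")
  if (cfg$planted_fraction < 0 || cfg$planted_fraction > 1)
    stop("planted_fraction outside [0, 1]")
  counts <- sample_planted_counts(cfg)
  if (cfg$planted_fraction == 0) counts[] <- 0L
  if (cfg$planted_fraction == 1) counts[] <- cfg$genes_per_sample
  set.seed(gen_seed(cfg, 2L) + 1L)
  fam_ids <- names(families$ancestors)
  cat_rows <- vector("list", cfg$n_samples)
  truth_rows <- vector("list", cfg$n_samples + 1L)
  for (i in seq_len(cfg$n_samples)) {
    sid <- sprintf("S%03d", i)
    n_pl <- counts[i]
    n_bg <- cfg$genes_per_sample - n_pl
    fams <- if (n_pl > 0L) sample(fam_ids, n_pl, replace = TRUE) else character(0)
    planted <- vapply(fams, function(f) {
      mutate_sequence(families$ancestors[[f]], cfg$within_family_divergence)
    }, character(1), USE.NAMES = FALSE)
    bg <- if (n_bg > 0L) random_aa(n_bg, cfg$seq_length) else character(0)
    ids <- sprintf("%s_g%04d", sid, seq_len(cfg$genes_per_sample))
    cat_rows[[i]] <- data.frame(gene_id = ids, sample_id = sid,
                                sequence = c(planted, bg),
                                stringsAsFactors = FALSE)
    truth_rows[[i]] <- data.frame(
      gene_id = ids,
      is_homolog = c(rep(TRUE, n_pl), rep(FALSE, n_bg)),
      source_family = c(fams, rep(NA_character_, n_bg)),
      stringsAsFactors = FALSE)
  }
  catalog <- do.call(rbind, cat_rows)

  ## control: half background, half composition-matched near-decoys
  n_decoy <- cfg$control_genes %/% 2L
  n_bg <- cfg$control_genes - n_decoy
  decoy_src <- sample(families$records$sequence, n_decoy, replace = TRUE)
  decoys <- vapply(decoy_src, shuffle_sequence, character(1), USE.NAMES = FALSE)
  ctl_ids <- sprintf("CTL_g%04d", seq_len(cfg$control_genes))
  control <- data.frame(gene_id = ctl_ids,
                        sequence = c(decoys, random_aa(n_bg, cfg$seq_length)),
                        stringsAsFactors = FALSE)
  truth_rows[[cfg$n_samples + 1L]] <- data.frame(
    gene_id = ctl_ids, is_homolog = FALSE, source_family = NA_character_,
    stringsAsFactors = FALSE)
  truth <- do.call(rbind, truth_rows)
  rownames(catalog) <- rownames(control) <- rownames(truth) <- NULL
  list(catalog = catalog, control = control, truth = truth,
       planted_counts = counts)
}

OCEAN_REGIONS <- c("Mediterranean Sea", "South Pacific Ocean",
                   "North Pacific Ocean", "South Atlantic Ocean",
                   "North Atlantic Ocean", "Indian Ocean",
                   "Arctic Ocean", "Red Sea")

#' Generate geolocated sample metadata
#'
#' Coordinates on a WGS-84-like sphere (decimal degrees), depths drawn from
#' three layer regimes (surface SRF, deep chlorophyll maximum DCM,
#' mesopelagic MES, with means ordered SRF < DCM < MES by construction),
#' region/habitat labels, a temperature covariate decreasing with depth, and
#' the latent pollution field value per sample.
#'
#' @param cfg a [generator_config()].
#' @return data frame: sample_id, lat, lon, depth_m, layer, habitat,
#'   temperature_c, pollution_field.
#' @export
generate_geo_metadata <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  field <- latent_field(cfg)
  set.seed(gen_seed(cfg, 4L))
  n <- cfg$n_samples
  lat <- runif(n, -65, 75)
  lon <- runif(n, -180, 180)
  layer <- sample(c("SRF", "DCM", "MES"), n, replace = TRUE,
                  prob = c(63, 46, 30) / 139)
  depth <- numeric(n)
  depth[layer == "SRF"] <- 5
  depth[layer == "DCM"] <- pmin(pmax(rnorm(sum(layer == "DCM"), 71, 41), 20), 150)
  depth[layer == "MES"] <- pmin(pmax(rnorm(sum(layer == "MES"), 600, 220), 250), 1100)
  habitat <- sample(OCEAN_REGIONS, n, replace = TRUE)
  temp <- 25 - 0.02 * depth + rnorm(n, 0, 2)
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             lat = lat, lon = lon, depth_m = depth, layer = layer,
             habitat = habitat, temperature_c = temp,
             pollution_field = field, stringsAsFactors = FALSE)
}

#' Generate pollution survey point tables
#'
#' Samples are assigned to surveys round-robin; each survey measures a noisy,
#' scale-distorted, monotone (exponential) transform of the latent field at
#' coordinates jittered around its samples. Together the surveys cover every
#' sample within a short radius, on deliberately incompatible measurement
#' scales, so pooling is required before correlation.
#'
#' @param cfg a [generator_config()].
#' @param metadata output of [generate_geo_metadata()].
#' @return list of data frames (one per survey): survey_id, lat, lon, value.
#' @export
generate_pollution_surveys <- function(cfg, metadata) {
  stopifnot(inherits(cfg, "generator_config"))
  if (nrow(metadata) == 0L) stop("metadata must be non-empty")
  set.seed(gen_seed(cfg, 5L))
  n <- nrow(metadata)
  survey_of <- ((seq_len(n) - 1L) %% cfg$n_surveys) + 1L
  lapply(seq_len(cfg$n_surveys), function(s) {
    idx <- which(survey_of == s)
    jit_lat <- runif(length(idx), -cfg$coord_jitter_deg, cfg$coord_jitter_deg)
    jit_lon <- runif(length(idx), -cfg$coord_jitter_deg, cfg$coord_jitter_deg)
    noise <- if (cfg$survey_noise_sd > 0)
      rnorm(length(idx), 0, cfg$survey_noise_sd) else 0
    data.frame(
      survey_id = sprintf("SURV%d", s),
      lat = pmin(pmax(metadata$lat[idx] + jit_lat, -90), 90),
      lon = ((metadata$lon[idx] + jit_lon + 180) %% 360) - 180,
      value = cfg$survey_scale_factors[s] *
        exp(metadata$pollution_field[idx] + noise),
      stringsAsFactors = FALSE)
  })
}
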