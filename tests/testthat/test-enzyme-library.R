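test_that("pairwise identity handles matches, mismatches and length differences", {
  expect_equal(pairwise_identity("AAAA", "AAAA"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 0.75)
  ## shorter-sequence denominator after global alignment
  expect_equal(pairwise_identity("AAAAAA", "AAA"), 1.0)
  expect_error(pairwise_identity("", "AAA"), "empty")
  ## symmetric, self-identity 1, agrees with a hand NW oracle
  s <- rand_seqs(6, 30, seed = 11)
  for (i in 1:3) {
    a <- s[2 * i - 1]; b <- s[2 * i]
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
    expect_equal(pairwise_identity(a, b), oracle_identity(a, b))
    expect_equal(pairwise_identity(a, a), 1.0)
  }
})

test_that("greedy clustering partitions input and matches the brute-force oracle", {
  recs <- data.frame(id = c("a", "b", "c"),
                     sequence = c("AAAA", "AAAA", "CCCC"))
  cl <- cluster_sequences(recs, 0.95)
  expect_length(cl, 2)
  expect_length(cluster_sequences(recs[1, ], 0.95), 1)

  ## 10 seeded random sequences at cutoff 0.6 vs the oracle partition
  set.seed(7)
  base <- rand_seqs(4, 40, seed = 7)
  seqs <- c(base, vapply(base, function(s) {
    x <- strsplit(s, "")[[1]]
    k <- sample(40, 10)
    x[k] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 10, TRUE)
    paste(x, collapse = "")
  }, character(1)), rand_seqs(2, 40, seed = 8))
  recs <- data.frame(id = sprintf("q%02d", seq_along(seqs)), sequence = seqs)
  got <- cluster_sequences(recs, 0.6)
  want <- oracle_cluster(recs, 0.6)
  expect_equal(lapply(got, `[[`, "member_ids"), want)
  ## clusters partition the input
  expect_setequal(unlist(lapply(got, `[[`, "member_ids")), recs$id)
  ## members meet the cutoff against their representative
  for (cl1 in got) {
    rep_seq <- recs$sequence[recs$id == cl1$representative_id]
    for (m in cl1$member_ids) {
      expect_gte(pairwise_identity(recs$sequence[recs$id == m], rep_seq), 0.6)
    }
  }
})

test_that("re-clustering representatives yields singletons (idempotence)", {
  cfg <- tiny_cfg()
  fam <- generate_enzyme_families(cfg)
  cl <- cluster_sequences(fam$records, 0.95)
  rep_ids <- vapply(cl, `[[`, character(1), "representative_id")
  reps <- fam$records[match(rep_ids, fam$records$id), ]
  cl2 <- cluster_sequences(reps, 0.95)
  expect_length(cl2, nrow(reps))
  expect_true(all(lengths(lapply(cl2, `[[`, "member_ids")) == 1))
})

test_that("homolog expansion bins are cumulative, monotone, and identity-driven", {
  cfg <- tiny_cfg(seed = 2)
  fam <- generate_enzyme_families(cfg)
  reps <- fam$records[fam$records$id %in% sprintf("F0%d_M1", 1:4), ]
  db <- fam$records
  exp <- expand_homologs(reps, db, seed = 5)
  grid <- round(seq(0.60, 0.90, 0.05), 2)
  for (rid in reps$id) {
    sub <- exp[exp$representative_id == rid, ]
    ## the representative itself is present in all 7 bins
    expect_setequal(sub$identity_bin[sub$db_id == rid], grid)
    ## monotone bins: looser cutoff is a superset
    bins <- split(sub$db_id, sub$identity_bin)
    for (k in seq_len(length(bins) - 1)) {
      expect_true(all(bins[[k + 1]] %in% bins[[k]]))
    }
  }
  ## members at divergence 0.2 sit in the low bins, never at 0.90
  others <- exp[exp$db_id != exp$representative_id, ]
  expect_gt(nrow(others), 0)
  expect_true(all(others$identity_bin <= 0.80))
  expect_true(all(others$identity >= others$identity_bin))
  ## bracket mode assigns exactly one bin per expanded sequence
  expb <- expand_homologs(reps, db, mode = "bracket", seed = 5)
  ob <- expb[expb$db_id != expb$representative_id, ]
  expect_false(anyDuplicated(paste(ob$representative_id, ob$db_id)) > 0)
})

test_that("a pure-background database expands nothing beyond the representative", {
  reps <- data.frame(id = "R1", sequence = rand_seqs(1, 80, seed = 1),
                     plastic_type = "PET", compound_class = "polymer")
  db <- data.frame(id = sprintf("bg%02d", 1:30),
                   sequence = rand_seqs(30, 80, seed = 2))
  exp <- expand_homologs(reps, db, seed = 3)
  expect_true(all(exp$db_id == "R1"))
})

test_that("model columns are pseudocounted member counts", {
  m1 <- build_model_group(data.frame(id = "x", sequence = "ACD"),
                          representative_id = "x", identity_bin = 0.6)
  M <- m1$payload$logodds
  expect_equal(ncol(M), 3)
  expect_equal(rownames(M)[apply(M, 2, which.max)], c("A", "C", "D"))

  ## identical members shrink toward the same argmax
  mm <- build_model_group(
    data.frame(id = c("x", "y", "z"), sequence = rep("ACD", 3)),
    representative_id = "x", identity_bin = 0.6)
  expect_equal(rownames(M)[apply(mm$payload$logodds, 2, which.max)],
               c("A", "C", "D"))

  ## 5 high-identity members: probabilities equal the direct
  ## (count+1)/(n+20) oracle (substitution-only variants align gap-free,
  ## so counts are column-wise letter tallies)
  seqs <- c("ACDEFGHIKLMN",
            "ACDEFGHIKLMW",
            "ACDEFGYIKLMN",
            "PCDEFGHIKLMN",
            "ACDEFGHIKRMN")
  ids <- sprintf("m%d", 1:5)
  g <- build_model_group(data.frame(id = ids, sequence = seqs),
                         representative_id = "m1", identity_bin = 0.6)
  chars <- do.call(rbind, strsplit(seqs, ""))
  aa <- rownames(g$payload$probs)
  for (j in c(1, 6, 12)) {
    counts <- table(factor(chars[, j], levels = aa))
    expect_equal(unname(g$payload$probs[, j]),
                 unname((as.numeric(counts) + 1) / (5 + 20)))
  }
})

test_that("library size is bounded by representatives x bins with inherited labels", {
  cfg <- tiny_cfg(seed = 4)
  fam <- generate_enzyme_families(cfg)
  lib <- build_library_from_catalog(fam$records, seed = 6)
  n_reps <- nrow(lib$representatives)
  expect_lte(nrow(lib$manifest), n_reps * 7)
  expect_true(all(lib$manifest$identity_bin %in% round(seq(0.6, 0.9, 0.05), 2)))
  expect_true(all(lib$manifest$n_members >= 1))
  ## plastic type inherited from the representative record
  idx <- match(lib$manifest$representative_id, fam$records$id)
  expect_equal(lib$manifest$plastic_type, fam$records$plastic_type[idx])
})
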