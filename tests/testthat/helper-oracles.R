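## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths (and Biostrings) so that implementation and
## check stay separate.

## plain Needleman-Wunsch, match +1 / mismatch 0 / linear gap -1;
## returns matches of the best global alignment
nw_matches <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)      # best score
  M <- matrix(0, n + 1, m + 1)      # matches along the best path
  S[, 1] <- -(0:n); S[1, ] <- -(0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      hit <- as.integer(x[i] == y[j])
      diag <- S[i, j] + hit
      up <- S[i, j + 1] - 1
      left <- S[i + 1, j] - 1
      best <- max(diag, up, left)
      S[i + 1, j + 1] <- best
      M[i + 1, j + 1] <- if (best == diag) M[i, j] + hit
                         else if (best == up) M[i, j + 1] else M[i + 1, j]
    }
  }
  M[n + 1, m + 1]
}

oracle_identity <- function(a, b) nw_matches(a, b) / min(nchar(a), nchar(b))

## greedy clustering re-done from scratch on top of oracle_identity
oracle_cluster <- function(records, cutoff) {
  ord <- order(-nchar(records$sequence), records$id)
  recs <- records[ord, ]
  reps <- character(0); out <- list()
  for (i in seq_len(nrow(recs))) {
    placed <- FALSE
    for (j in seq_along(reps)) {
      if (oracle_identity(recs$sequence[i], reps[j]) >= cutoff) {
        out[[j]] <- c(out[[j]], recs$id[i]); placed <- TRUE; break
      }
    }
    if (!placed) {
      reps <- c(reps, recs$sequence[i])
      out[[length(reps)]] <- recs$id[i]
    }
  }
  out
}

## spherical law-of-haversines distance, written out longhand
oracle_haversine <- function(lat1, lon1, lat2, lon2, R = 6371.0088) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  a <- sin((p2 - p1) / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * R * asin(sqrt(pmin(1, a)))
}

## random amino-acid sequences for fixtures
rand_seqs <- function(n, L, seed) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n),
         function(i) paste(sample(aa, L, replace = TRUE), collapse = ""),
         character(1))
}

## small generator config shared by the unit tests (fast: short sequences,
## few samples); the acceptance test runs the full defaults
tiny_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_families = 4, family_size = 3, seq_length = 120,
         n_samples = 12, genes_per_sample = 25, control_genes = 120),
    list(...))
  do.call(generator_config, args)
}
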