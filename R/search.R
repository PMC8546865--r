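## Surrogate homology scorer: best ungapped-window log-odds score of each
## gene against each model, with empirical decoy-calibrated E-values, plus a
## reader/writer for the standard per-target tabular search output and
## best-hit-per-gene deduplication.

## score one integer-coded sequence against a log-odds matrix: best ungapped
## full-overlap window of the shorter within the longer
score_one <- function(code, M) {
  L <- ncol(M)
  n <- length(code)
  ok <- !is.na(code)
  if (n == L) {
    return(sum(M[cbind(code[ok], seq_len(L)[ok])]))
  }
  if (n > L) {
    best <- -Inf
    for (o in 0:(n - L)) {
      w <- code[(o + 1):(o + L)]
      k <- !is.na(w)
      s <- sum(M[cbind(w[k], seq_len(L)[k])])
      if (s > best) best <- s
    }
  } else {
    best <- -Inf
    for (o in 0:(L - n)) {
      k <- ok
      s <- sum(M[cbind(code[k], (o + seq_len(n))[k])])
      if (s > best) best <- s
    }
  }
  best
}

## precomputed index matrix for the vectorized same-length scoring path:
## codes + 20 * (column - 1), NA-safe (NAs map to index 1 and are masked)
precompute_idx <- function(seqs, L) {
  lens <- nchar(seqs)
  if (length(seqs) == 0L || any(lens != L)) return(NULL)
  codes <- aa_matrix(seqs)
  nas <- is.na(codes)
  codes[nas] <- 1L
  idx <- codes + matrix(20L * (seq_len(L) - 1L), nrow = nrow(codes),
                        ncol = L, byrow = TRUE)
  list(idx = idx, nas = nas, n = nrow(codes))
}

score_with_idx <- function(pre, M) {
  v <- M[pre$idx]
  v[pre$nas] <- 0
  rowSums(matrix(v, nrow = pre$n))
}

#' Score sequences against a profile model
#'
#' Best ungapped window log-odds score (bits) of each sequence against the
#' model's position-specific matrix. Sequences the same length as the model
#' use a vectorized single-offset path.
#'
#' @param seqs character vector of amino-acid sequences.
#' @param model a `profile_model_group`.
#' @return numeric vector of bit scores.
#' @export
score_sequences <- function(seqs, model) {
  M <- model$payload$logodds
  if (is.null(M)) stop("model payload incompatible with the built-in scorer")
  L <- ncol(M)
  lens <- nchar(seqs)
  out <- numeric(length(seqs))
  same <- lens == L
  if (any(same)) {
    codes <- aa_matrix(seqs[same])
    idx <- codes + matrix(20L * (seq_len(L) - 1L), nrow = nrow(codes),
                          ncol = L, byrow = TRUE)
    v <- M[idx]
    v[is.na(v)] <- 0
    out[same] <- rowSums(matrix(v, nrow = nrow(codes)))
  }
  for (i in which(!same)) out[i] <- score_one(aa_to_int(seqs[i]), M)
  out
}

#' Seeded residue-shuffle decoys
#'
#' @param seqs catalog sequences to shuffle (sampled with replacement).
#' @param n_decoys number of decoy sequences.
#' @param seed RNG seed.
#' @return character vector of decoy sequences.
#' @export
make_decoys <- function(seqs, n_decoys, seed = 1L) {
  set.seed(seed)
  src <- sample(seqs, n_decoys, replace = TRUE)
  vapply(src, shuffle_sequence, character(1), USE.NAMES = FALSE)
}

#' Empirical decoy-calibrated E-values
#'
#' Within the decoy score range, the plus-one-smoothed empirical estimate
#' `E(s) = n_catalog * (1 + #\{decoy >= s\}) / (1 + n_decoys)`; beyond the top
#' decoy score the tail is extended as `E(s_max) * 2^-(s - s_max)` — scores
#' are log2 odds (bits), so each extra bit halves the expected chance-match
#' count. The result is non-increasing in the score.
#'
#' @param scores bit scores to calibrate.
#' @param decoy_sorted sorted (ascending) decoy bit scores.
#' @param n_catalog catalog size (the E-value database-size factor).
#' @return numeric vector of E-values, same length as `scores`.
#' @export
empirical_evalue <- function(scores, decoy_sorted, n_catalog) {
  n_dec <- length(decoy_sorted)
  ## #{decoy >= s} = n_dec - #{decoy < s}
  n_lt <- findInterval(scores, decoy_sorted, left.open = TRUE)
  cnt_ge <- n_dec - n_lt
  ev <- n_catalog * (1 + cnt_ge) / (1 + n_dec)
  smax <- decoy_sorted[n_dec]
  tail <- scores > smax
  ev[tail] <- n_catalog / (1 + n_dec) * 2^(-(scores[tail] - smax))
  ev
}

#' Score a gene catalog against the model library
#'
#' Each gene is scored against every model; empirical E-values are calibrated
#' against one shared set of seeded residue-shuffle decoys drawn from the
#' catalog itself. Hits with `E <= evalue_report_max` are emitted.
#'
#' @param library output of [build_model_library()] (or a list of models).
#' @param catalog data frame: `gene_id`, `sequence`, optional `sample_id`.
#' @param evalue_report_max report threshold (loose by default so that the
#'   calibration stage sees control hits).
#' @param origin `"environmental"` or `"control"` tag on every hit.
#' @param n_decoys decoy scores per model (default 10000).
#' @param seed seed for the decoy shuffles.
#' @return hit table: data frame (`gene_id`, `sample_id`, `model_id`,
#'   `bit_score`, `evalue`, `origin`) with scorer provenance attributes.
#' @export
score_catalog <- function(library, catalog, evalue_report_max = 10,
                          origin = c("environmental", "control"),
                          n_decoys = 10000L, seed = 1L) {
  origin <- match.arg(origin)
  models <- if (!is.null(library$models)) library$models else library
  if (!length(models)) stop("score_catalog: empty model library")
  sample_id <- if ("sample_id" %in% names(catalog)) catalog$sample_id
               else rep(NA_character_, nrow(catalog))
  decoys <- make_decoys(catalog$sequence, n_decoys, seed = seed)
  n_cat <- nrow(catalog)
  ## when catalog and models share one length, precompute the index matrices
  ## once and reuse them for every model
  L0 <- ncol(models[[1]]$payload$logodds)
  same_L <- all(vapply(models, function(m) ncol(m$payload$logodds),
                       numeric(1)) == L0)
  pre_cat <- if (same_L) precompute_idx(catalog$sequence, L0) else NULL
  pre_dec <- if (same_L) precompute_idx(decoys, L0) else NULL
  rows <- vector("list", length(models))
  for (k in seq_along(models)) {
    m <- models[[k]]
    if (!is.null(pre_cat) && !is.null(pre_dec)) {
      M <- m$payload$logodds
      sc <- score_with_idx(pre_cat, M)
      dsc <- sort(score_with_idx(pre_dec, M))
    } else {
      sc <- score_sequences(catalog$sequence, m)
      dsc <- sort(score_sequences(decoys, m))
    }
    ev <- empirical_evalue(sc, dsc, n_cat)
    keep <- which(ev <= evalue_report_max)
    if (length(keep)) {
      rows[[k]] <- data.frame(gene_id = catalog$gene_id[keep],
                              sample_id = sample_id[keep],
                              model_id = m$model_id,
                              bit_score = sc[keep], evalue = ev[keep],
                              origin = origin, stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, rows)
  if (is.null(hits)) {
    hits <- data.frame(gene_id = character(0), sample_id = character(0),
                       model_id = character(0), bit_score = numeric(0),
                       evalue = numeric(0), origin = character(0),
                       stringsAsFactors = FALSE)
  }
  rownames(hits) <- NULL
  attr(hits, "scorer") <- "plasticmine-window-logodds"
  attr(hits, "n_decoys") <- n_decoys
  attr(hits, "seed") <- seed
  attr(hits, "evalue_report_max") <- evalue_report_max
  hits
}

#' Keep the single best hit per gene
#'
#' The hit with the lowest E-value is retained for each gene; ties are broken
#' by the larger bit score, then by lexicographic model id. With
#' `per_model = TRUE` the reduction is per (gene, model) pair instead.
#'
#' @param hits raw hit table.
#' @param per_model reduce per gene-model pair instead of globally per gene.
#' @return deduplicated hit table (one row per gene, or per gene-model pair).
#' @export
deduplicate_hits <- function(hits, per_model = FALSE) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$gene_id, hits$evalue, -hits$bit_score, hits$model_id)
  h <- hits[ord, , drop = FALSE]
  key <- if (per_model) paste(h$gene_id, h$model_id, sep = "\r") else h$gene_id
  out <- h[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read per-target tabular search output
#'
#' Parses the standard whitespace-delimited per-target table (comment lines
#' start with `#`; fields: target name, target accession, query name, query
#' accession, full-sequence E-value, full-sequence score, ...). The target is
#' the gene, the query the model.
#'
#' @param path file path.
#' @param origin `"environmental"` or `"control"` tag.
#' @param sample_map optional named character vector gene_id -> sample_id.
#' @return raw hit table as in [score_catalog()].
#' @export
read_search_table <- function(path, origin = c("environmental", "control"),
                              sample_map = NULL) {
  origin <- match.arg(origin)
  lines <- readLines(path)
  data_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(data_idx)) {
    return(data.frame(gene_id = character(0), sample_id = character(0),
                      model_id = character(0), bit_score = numeric(0),
                      evalue = numeric(0), origin = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines[data_idx]), "[ \t]+")
  bad <- which(vapply(fields, length, integer(1)) < 6L)
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 6L) return(NULL)
    ev <- suppressWarnings(as.numeric(f[5]))
    sc <- suppressWarnings(as.numeric(f[6]))
    if (is.na(ev) || is.na(sc)) {
      bad <<- c(bad, i)
      return(NULL)
    }
    data.frame(gene_id = f[1], model_id = f[3], evalue = ev, bit_score = sc,
               stringsAsFactors = FALSE)
  })
  if (length(bad)) {
    stop("read_search_table: malformed rows at line(s) ",
         paste(sort(unique(data_idx[bad])), collapse = ", "), " of ", path)
  }
  df <- do.call(rbind, rows)
  df$sample_id <- if (is.null(sample_map)) NA_character_
                  else unname(sample_map[df$gene_id])
  df$origin <- origin
  df[, c("gene_id", "sample_id", "model_id", "bit_score", "evalue", "origin")]
}

#' Write a hit table in the per-target tabular dialect
#'
#' @param hits hit table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_search_table <- function(hits, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# target name  accession  query name  accession  E-value  score",
               "#"), con)
  if (nrow(hits)) {
    writeLines(sprintf("%s - %s - %.6g %.6g", hits$gene_id, hits$model_id,
                       hits$evalue, hits$bit_score), con)
  }
  invisible(path)
}
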