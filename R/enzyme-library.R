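## Identity-stratified model library: representative clustering of the
## curated enzyme catalog, homolog expansion against a sequence database
## across a 60-90% identity grid, and position-specific log-odds model
## construction.

IDENTITY_GRID <- round(seq(0.60, 0.90, by = 0.05), 2)

## +1 match / 0 mismatch substitution matrix over the 20 residues plus X
## (X never matches, including X vs X)
identity_submat <- local({
  letters <- c(AA20, "X")
  m <- matrix(0, 21, 21, dimnames = list(letters, letters))
  diag(m) <- 1
  m["X", "X"] <- 0
  m
})

#' Global-alignment sequence identity
#'
#' Identity is the number of matching columns of a global alignment
#' (match +1, mismatch 0, linear gap -1) divided by the length of the
#' shorter sequence, mirroring the default semantics of the usual greedy
#' clustering tools.
#'
#' @param a,b amino-acid strings (20 standard residues plus `X`).
#' @return fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("pairwise_identity: empty sequence")
  identity_to_many(a, b)
}

## identity of each of `seqs` to a single reference (vectorized alignment)
identity_to_many <- function(ref, seqs) {
  if (!nzchar(ref) || any(!nzchar(seqs)))
    stop("pairwise_identity: empty sequence")
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(seqs),
    subject = Biostrings::AAString(ref),
    substitutionMatrix = identity_submat,
    gapOpening = 0, gapExtension = 1, type = "global")
  Biostrings::nmatch(al) / pmin(nchar(seqs), nchar(ref))
}

#' Greedy incremental identity clustering
#'
#' Records are visited in deterministic order (length descending, ties by
#' lexicographic id); each joins the first existing cluster whose
#' representative it matches at `>= cutoff`, else founds a new cluster.
#' Clusters partition the input; every member's identity to its
#' representative is `>= cutoff` by construction.
#'
#' @param records data frame with columns `id` and `sequence`.
#' @param cutoff identity cutoff in `(0, 1]`.
#' @return list of clusters, each `list(representative_id, member_ids,
#'   identity_cutoff)`.
#' @export
cluster_sequences <- function(records, cutoff) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  ord <- order(-nchar(records$sequence), records$id)
  recs <- records[ord, , drop = FALSE]
  reps <- character(0)      # representative sequences, founding order
  rep_ids <- character(0)
  members <- list()
  for (i in seq_len(nrow(recs))) {
    s <- recs$sequence[i]
    placed <- FALSE
    if (length(reps)) {
      ident <- identity_to_many(s, reps)   # identity of s to each rep
      j <- which(ident >= cutoff)
      if (length(j)) {
        j <- j[1L]
        members[[j]] <- c(members[[j]], recs$id[i])
        placed <- TRUE
      }
    }
    if (!placed) {
      reps <- c(reps, s)
      rep_ids <- c(rep_ids, recs$id[i])
      members <- c(members, list(recs$id[i]))
    }
  }
  lapply(seq_along(rep_ids), function(j) {
    list(representative_id = rep_ids[j], member_ids = members[[j]],
         identity_cutoff = cutoff)
  })
}

#' Expand representatives with database homologs across the identity grid
#'
#' Database sequences matching a representative at E-value below `evalue_max`
#' are assigned to identity bins. In the default `"cumulative"` mode a
#' sequence enters every bin whose cutoff its identity meets (a sequence at
#' 0.8 identity appears in bins 0.60-0.80); in `"bracket"` mode only its own
#' identity bracket. Each bin always includes the representative itself.
#'
#' E-values come either from the built-in decoy-calibrated scorer (each
#' representative scored as a single-sequence model against the database) or
#' from a precomputed table (e.g. an external search tool's output).
#'
#' @param representatives data frame with `id`, `sequence` columns.
#' @param database data frame with `id`, `sequence` columns.
#' @param evalue_max E-value inclusion cutoff (default 1e-10).
#' @param identity_grid bin cutoffs (default 0.60-0.90 step 0.05).
#' @param mode `"cumulative"` (default) or `"bracket"`.
#' @param evalues optional data frame (`representative_id`, `db_id`,
#'   `evalue`) replacing the built-in scorer.
#' @param n_decoys decoy scores per representative for the built-in scorer.
#' @param seed seed for decoy shuffles.
#' @return data frame (`representative_id`, `identity_bin`, `db_id`,
#'   `identity`); the representative itself appears in every bin with
#'   identity 1.
#' @export
expand_homologs <- function(representatives, database, evalue_max = 1e-10,
                            identity_grid = IDENTITY_GRID,
                            mode = c("cumulative", "bracket"),
                            evalues = NULL, n_decoys = 2000L, seed = 1L) {
  mode <- match.arg(mode)
  if (nrow(database) == 0L) stop("expand_homologs: empty database")
  if (evalue_max <= 0) stop("evalue_max must be > 0")
  identity_grid <- sort(round(identity_grid, 2))
  if (is.null(evalues)) {
    decoys <- make_decoys(database$sequence, n_decoys, seed = seed)
    L0 <- nchar(representatives$sequence[1])
    same_L <- all(nchar(representatives$sequence) == L0)
    pre_db <- if (same_L) precompute_idx(database$sequence, L0) else NULL
    pre_dec <- if (same_L) precompute_idx(decoys, L0) else NULL
    evalues <- do.call(rbind, lapply(seq_len(nrow(representatives)), function(r) {
      model <- build_model_group(
        representatives[r, c("id", "sequence")],
        representative_id = representatives$id[r], identity_bin = NA_real_)
      if (!is.null(pre_db) && !is.null(pre_dec)) {
        M <- model$payload$logodds
        sc <- score_with_idx(pre_db, M)
        dsc <- sort(score_with_idx(pre_dec, M))
      } else {
        sc <- score_sequences(database$sequence, model)
        dsc <- sort(score_sequences(decoys, model))
      }
      data.frame(representative_id = representatives$id[r],
                 db_id = database$id,
                 evalue = empirical_evalue(sc, dsc, nrow(database)),
                 stringsAsFactors = FALSE)
    }))
  }
  db_seq <- stats::setNames(database$sequence, database$id)
  out <- lapply(seq_len(nrow(representatives)), function(r) {
    rid <- representatives$id[r]
    rseq <- representatives$sequence[r]
    ev <- evalues[evalues$representative_id == rid, , drop = FALSE]
    keep <- ev$db_id[ev$evalue < evalue_max & ev$db_id != rid]
    ident <- if (length(keep)) identity_to_many(rseq, db_seq[keep]) else numeric(0)
    rows <- list(data.frame(representative_id = rid,
                            identity_bin = identity_grid, db_id = rid,
                            identity = 1, stringsAsFactors = FALSE))
    for (k in seq_along(keep)) {
      qual <- identity_grid[identity_grid <= ident[k]]
      if (!length(qual)) next
      if (mode == "bracket") qual <- max(qual)
      rows[[length(rows) + 1L]] <- data.frame(
        representative_id = rid, identity_bin = qual,
        db_id = unname(keep[k]), identity = unname(ident[k]),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build a profile scoring model from a bin's member sequences
#'
#' Every member is globally aligned to the representative; representative
#' columns yield per-column residue counts, converted to probabilities with
#' plus-one pseudocounts, `(count + 1) / (n + 20)`, and to a log2-odds matrix
#' against the background `q` (uniform by default). The payload (matrix +
#' background) is what the built-in scorer consumes; external builders may
#' supply their own opaque payload under the same contract.
#'
#' @param members data frame with `id`, `sequence`; must include the
#'   representative.
#' @param representative_id id of the representative within `members`.
#' @param identity_bin the bin cutoff this model belongs to.
#' @param plastic_type,compound_class labels inherited from the
#'   representative's catalog record.
#' @param background residue background frequencies (length 20).
#' @return object of class `profile_model_group`.
#' @export
build_model_group <- function(members, representative_id,
                              identity_bin = NA_real_,
                              plastic_type = NA_character_,
                              compound_class = NA_character_,
                              background = rep(1 / 20, 20)) {
  stopifnot(nrow(members) >= 1L)
  rep_seq <- members$sequence[match(representative_id, members$id)]
  if (is.na(rep_seq)) stop("representative not among members")
  L <- nchar(rep_seq)
  counts <- matrix(0L, nrow = 20L, ncol = L, dimnames = list(AA20, NULL))
  for (i in seq_len(nrow(members))) {
    s <- members$sequence[i]
    if (identical(s, rep_seq)) {
      code <- aa_to_int(s)
      ok <- !is.na(code)
      counts[cbind(code[ok], which(ok))] <- counts[cbind(code[ok], which(ok))] + 1L
      next
    }
    al <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(s),
      subject = Biostrings::AAString(rep_seq),
      substitutionMatrix = identity_submat,
      gapOpening = 0, gapExtension = 1, type = "global")
    pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    rep_cols <- which(sub != "-")
    res <- pat[rep_cols]                  # member residue at each rep column
    code <- match(res, AA20)              # gaps / X contribute nothing
    ok <- !is.na(code)
    idx <- cbind(code[ok], seq_len(L)[ok])
    counts[idx] <- counts[idx] + 1L
  }
  n <- nrow(members)
  probs <- (counts + 1) / (n + 20)
  logodds <- log2(probs / background)
  model_id <- if (is.na(identity_bin)) {
    paste0(representative_id, "_rep")
  } else {
    sprintf("%s_id%02d", representative_id, round(identity_bin * 100))
  }
  structure(list(model_id = model_id, representative_id = representative_id,
                 identity_bin = identity_bin, member_ids = members$id,
                 plastic_type = plastic_type, compound_class = compound_class,
                 payload = list(logodds = logodds, background = background,
                                probs = probs, length = L, n_members = n)),
            class = "profile_model_group")
}

#' @export
print.profile_model_group <- function(x, ...) {
  cat(sprintf("<profile_model_group %s: %d members, bin %s, type %s>\n",
              x$model_id, length(x$member_ids),
              ifelse(is.na(x$identity_bin), "-", format(x$identity_bin)),
              x$plastic_type))
  invisible(x)
}

#' Build the full identity-stratified model library
#'
#' One model per (representative, non-empty identity bin) pair, with plastic
#' type and compound class inherited from the representative's catalog
#' record.
#'
#' @param representatives data frame: `id`, `sequence`, `plastic_type`,
#'   `compound_class`.
#' @param expansion output of [expand_homologs()].
#' @param database data frame (`id`, `sequence`) the expansion drew from.
#' @return list with `models` (list of `profile_model_group`) and `manifest`
#'   (data frame: model_id, representative_id, identity_bin, n_members,
#'   plastic_type, compound_class).
#' @export
build_model_library <- function(representatives, expansion, database) {
  seq_of <- stats::setNames(
    c(representatives$sequence, database$sequence),
    c(representatives$id, database$id))
  key <- interaction(expansion$representative_id, expansion$identity_bin,
                     drop = TRUE)
  groups <- split(expansion, key)
  models <- lapply(groups, function(g) {
    rid <- g$representative_id[1]
    ids <- unique(g$db_id)
    r <- match(rid, representatives$id)
    build_model_group(
      data.frame(id = ids, sequence = unname(seq_of[ids]),
                 stringsAsFactors = FALSE),
      representative_id = rid, identity_bin = g$identity_bin[1],
      plastic_type = representatives$plastic_type[r],
      compound_class = representatives$compound_class[r])
  })
  names(models) <- vapply(models, `[[`, character(1), "model_id")
  models <- models[order(names(models))]
  manifest <- do.call(rbind, lapply(models, function(m) {
    data.frame(model_id = m$model_id, representative_id = m$representative_id,
               identity_bin = m$identity_bin,
               n_members = length(m$member_ids),
               plastic_type = m$plastic_type,
               compound_class = m$compound_class, stringsAsFactors = FALSE)
  }))
  rownames(manifest) <- NULL
  list(models = models, manifest = manifest)
}
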