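## Ecological statistics: tie-aware Spearman correlation, rank-sum habitat
## scans (exact for small groups), one-tailed hypergeometric enrichment,
## Bray-Curtis distances and principal-coordinate analysis.

#' Spearman rank correlation with a t-approximation p-value
#'
#' Average ranks for ties; rho is the Pearson correlation of the ranks; the
#' two-sided p-value uses the t approximation on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return list (`rho`, `p_value`, `n`, `degenerate`); `rho` is `NA` and
#'   `degenerate = TRUE` when either argument has zero rank variance.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  n <- length(x)
  if (var(rank(x)) == 0 || var(rank(y)) == 0) {
    warning("spearman_cor: zero rank variance; rho undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = n, degenerate = TRUE))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
       degenerate = FALSE)
}

## exact rank-sum p by full enumeration of group assignments (handles ties);
## feasible for combined n <= ~14
rank_sum_enumerate <- function(g, r, alternative) {
  pooled <- c(g, r)
  rk <- rank(pooled)
  n1 <- length(g)
  t_obs <- sum(rk[seq_len(n1)])
  sets <- combn(length(pooled), n1)
  ts <- apply(sets, 2, function(idx) sum(rk[idx]))
  p_le <- mean(ts <= t_obs)
  p_ge <- mean(ts >= t_obs)
  switch(alternative,
         less = p_le,
         greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

#' Rank-sum (Mann-Whitney) test of one group against another
#'
#' Backends: exact Wilcoxon distribution for untied data (any moderate n),
#' full enumeration for tied data with combined `n <= 12`, otherwise the
#' tie-corrected normal approximation (no continuity correction, which
#' tracks the exact two-sided p more closely at these sizes).
#'
#' @param group,rest numeric vectors, both non-empty.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (`group` against `rest`).
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @return list (`statistic` — the Mann-Whitney U of `group`, `p_value`,
#'   `method`).
#' @export
rank_sum <- function(group, rest, alternative = c("two.sided", "greater", "less"),
                     method = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  stopifnot(length(group) >= 1, length(rest) >= 1)
  n_tot <- length(group) + length(rest)
  has_ties <- anyDuplicated(c(group, rest)) > 0
  if (method == "auto") {
    method <- if ((!has_ties && n_tot <= 50) || (has_ties && n_tot <= 12))
      "exact" else "normal"
  }
  U <- unname(suppressWarnings(
    stats::wilcox.test(group, rest, alternative = alternative,
                       exact = FALSE)$statistic))
  if (method == "exact") {
    p <- if (has_ties) {
      if (n_tot > 14) stop("rank_sum: exact enumeration infeasible for tied n > 14")
      rank_sum_enumerate(group, rest, alternative)
    } else {
      stats::wilcox.test(group, rest, alternative = alternative,
                         exact = TRUE)$p.value
    }
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(group, rest, alternative = alternative,
                         exact = FALSE, correct = FALSE)$p.value)
  }
  list(statistic = U, p_value = p, method = method)
}

#' One-tailed Fisher enrichment p-value on a 2x2 table
#'
#' Hypergeometric upper tail `P(X >= a)` with the table's margins fixed,
#' where `a` is the top-left cell.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return p-value.
#' @export
fisher_one_tailed <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2), all(tab >= 0),
            all(tab == round(tab)))
  if (sum(tab) == 0) stop("fisher_one_tailed: all-zero table")
  a <- tab[1, 1]
  m <- sum(tab[, 1])              # first-column margin (successes)
  n <- sum(tab[, 2])
  k <- sum(tab[1, ])              # first-row margin (draws)
  stats::phyper(a - 1, m, n, k, lower.tail = FALSE)
}

#' Bray-Curtis distance matrix
#'
#' `d(u, v) = 1 - 2 * sum_i min(u_i, v_i) / (sum u + sum v)` over sample
#' count rows.
#'
#' @param counts samples x features matrix/data frame of non-negative
#'   counts.
#' @return symmetric distance matrix with zero diagonal; pairs of all-zero
#'   rows yield `NaN` and all-zero rows are flagged in the `"zero_rows"`
#'   attribute.
#' @export
bray_curtis_matrix <- function(counts) {
  m <- as.matrix(counts)
  if (any(m < 0)) stop("bray_curtis_matrix: negative entries")
  zero_rows <- which(rowSums(m) == 0)
  if (length(zero_rows))
    warning("bray_curtis_matrix: ", length(zero_rows), " all-zero row(s)")
  d <- as.matrix(suppressWarnings(vegan::vegdist(m, method = "bray")))
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  attr(d, "zero_rows") <- zero_rows
  d
}

#' Principal-coordinate analysis (classical metric scaling)
#'
#' Double-centers `-D^2/2` and eigendecomposes; axes are ordered by
#' eigenvalue, negative eigenvalues are dropped from the
#' variance-explained denominator (sum of positive eigenvalues), and no
#' Lingoes/Cailliez correction is applied.
#'
#' @param distances square symmetric matrix with zero diagonal.
#' @param k number of axes to return (default: all positive-eigenvalue
#'   axes).
#' @return list (`coordinates` n x k, `variance_explained` fractions,
#'   `eigenvalues`).
#' @export
pcoa_ordination <- function(distances, k = NULL) {
  d <- as.matrix(distances)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("pcoa_ordination: non-symmetric input")
  n <- nrow(d)
  ## cmdscale warns when fewer than k eigenvalues are positive; the
  ## positive-eigenvalue screen below handles that case
  mds <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- mds$eig
  tol <- max(abs(eig)) * 1e-8
  pos <- which(eig > tol)
  ve <- eig[pos] / sum(eig[pos])
  if (is.null(k)) k <- length(pos)
  k <- min(k, length(pos))
  coords <- mds$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coordinates = coords, variance_explained = ve[seq_len(k)],
       eigenvalues = eig)
}

#' One-vs-rest rank-sum scan over sample groups
#'
#' For each group, its samples' values are tested against all other
#' samples'. No multiplicity correction is applied.
#'
#' @param values numeric per-sample values (e.g. hit counts).
#' @param groups group label per sample.
#' @param alternative passed to [rank_sum()].
#' @return data frame (`group`, `n`, `statistic`, `p_value`); empty groups
#'   are skipped with a message.
#' @export
habitat_scan <- function(values, groups,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(values) == length(groups))
  labs <- unique(groups)
  if (length(labs) < 2) stop("habitat_scan: need >= 2 groups")
  rows <- lapply(labs, function(g) {
    sel <- groups == g
    if (!any(sel) || all(sel)) {
      message("habitat_scan: skipping degenerate group '", g, "'")
      return(NULL)
    }
    rs <- rank_sum(values[sel], values[!sel], alternative = alternative)
    data.frame(group = g, n = sum(sel), statistic = rs$statistic,
               p_value = rs$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
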