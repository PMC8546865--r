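## Negative-control calibration: per-model precision-recall of environmental
## vs control hit scores, PR-AUC and minimum-points gates, and the precision
## score threshold that the final hit filter enforces together with the
## E-value cutoff.

#' Filter configuration (defaults: the study's gates)
#'
#' @param precision_target precision the score threshold must reach (0.9999).
#' @param auc_min minimum PR-AUC for a model to be retained (0.75).
#' @param min_points minimum labeled points per model (20).
#' @param evalue_max E-value cutoff on final hits (1e-16).
#' @param points `"combined"` (environmental + control hits count toward
#'   `min_points`, the default reading) or `"env_only"`.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(precision_target = 0.9999, auc_min = 0.75,
                          min_points = 20L, evalue_max = 1e-16,
                          points = c("combined", "env_only")) {
  stopifnot(precision_target > 0, precision_target <= 1,
            auc_min >= 0, auc_min <= 1, min_points >= 1, evalue_max > 0)
  structure(list(precision_target = precision_target, auc_min = auc_min,
                 min_points = as.integer(min_points), evalue_max = evalue_max,
                 points = match.arg(points)),
            class = "filter_config")
}

#' Precision-recall curve of environmental vs control scores
#'
#' Environmental hits are the positives, control hits the negatives. One
#' point per distinct score threshold, descending; tied scores share a
#' threshold. At threshold `t`, precision and recall are computed over
#' entries with score `>= t`.
#'
#' @param scores numeric bit scores.
#' @param labels character, `"environmental"` or `"control"`, parallel to
#'   `scores`.
#' @return data frame (`threshold`, `precision`, `recall`), thresholds
#'   descending.
#' @export
precision_recall_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  pos <- labels == "environmental"
  P <- sum(pos)
  if (P == 0L) stop("precision_recall_curve: zero environmental entries")
  ord <- order(-scores)
  s <- scores[ord]
  tp <- cumsum(pos[ord])
  n_ge <- seq_along(s)
  last <- !duplicated(s, fromLast = TRUE)   # last index of each distinct score
  data.frame(threshold = s[last],
             precision = tp[last] / n_ge[last],
             recall = tp[last] / P)
}

#' Area under the precision-recall curve
#'
#' `"trapezoid"` (default): trapezoidal area over recall, anchored at
#' `(recall = 0, precision = precision of the highest-score point)`.
#' `"step"`: the step-wise average-precision alternative,
#' `sum (r_i - r_{i-1}) * p_i`.
#'
#' @param curve output of [precision_recall_curve()].
#' @param method `"trapezoid"` or `"step"`.
#' @return area in `[0, 1]`.
#' @export
pr_auc <- function(curve, method = c("trapezoid", "step")) {
  method <- match.arg(method)
  stopifnot(nrow(curve) >= 1L)
  r <- c(0, curve$recall)
  p <- c(curve$precision[1], curve$precision)
  dr <- diff(r)
  if (method == "trapezoid") {
    sum(dr * (p[-1] + p[-length(p)]) / 2)
  } else {
    sum(dr * p[-1])
  }
}

#' Calibrate one model against its labeled scores
#'
#' Gates, in order: at least `min_points` labeled points; PR-AUC at least
#' `auc_min`; a score threshold exists — the smallest distinct score whose
#' precision reaches `precision_target`. A model is retained only if all
#' gates pass; `reasons` lists every failed gate.
#'
#' @param scores,labels labeled bit scores as in [precision_recall_curve()].
#' @param cfg a [filter_config()].
#' @param model_id optional id recorded in the result.
#' @return list (`model_id`, `n_points`, `n_env`, `n_control`, `auc`,
#'   `score_threshold`, `retained`, `reasons`).
#' @export
calibrate_model <- function(scores, labels, cfg = filter_config(),
                            model_id = NA_character_) {
  n_env <- sum(labels == "environmental")
  n_ctl <- sum(labels == "control")
  n_points <- if (cfg$points == "env_only") n_env else n_env + n_ctl
  reasons <- character(0)
  auc <- NA_real_
  thr <- NA_real_
  if (n_points < cfg$min_points) reasons <- c(reasons, "min_points")
  if (n_env > 0L) {
    curve <- precision_recall_curve(scores, labels)
    auc <- pr_auc(curve)
    if (auc < cfg$auc_min) reasons <- c(reasons, "auc")
    ok <- curve$precision >= cfg$precision_target
    if (any(ok)) thr <- min(curve$threshold[ok])
    else reasons <- c(reasons, "precision_threshold")
  } else {
    reasons <- c(reasons, "auc", "precision_threshold")
  }
  list(model_id = model_id, n_points = n_points, n_env = n_env,
       n_control = n_ctl, auc = auc, score_threshold = thr,
       retained = length(reasons) == 0L, reasons = reasons)
}

#' Calibrate every model in the library
#'
#' Builds per-model labeled score sets from deduplicated environmental and
#' control hit tables and applies [calibrate_model()] to each. Models with no
#' hits at all are reported as not retained.
#'
#' @param env_hits,control_hits deduplicated hit tables.
#' @param manifest library manifest (all model ids).
#' @param cfg a [filter_config()].
#' @return calibration report data frame (`model_id`, `n_points`, `n_env`,
#'   `n_control`, `auc`, `score_threshold`, `retained`, `reasons`).
#' @export
calibrate_library <- function(env_hits, control_hits, manifest,
                              cfg = filter_config()) {
  all_hits <- rbind(env_hits[, c("model_id", "bit_score", "origin")],
                    control_hits[, c("model_id", "bit_score", "origin")])
  res <- lapply(manifest$model_id, function(mid) {
    h <- all_hits[all_hits$model_id == mid, , drop = FALSE]
    r <- calibrate_model(h$bit_score, h$origin, cfg, model_id = mid)
    data.frame(model_id = mid, n_points = r$n_points, n_env = r$n_env,
               n_control = r$n_control, auc = r$auc,
               score_threshold = r$score_threshold, retained = r$retained,
               reasons = paste(r$reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Apply the calibration filter to environmental hits
#'
#' A hit survives iff its model is retained, its E-value is below
#' `cfg$evalue_max`, and its bit score is at least the model's score
#' threshold.
#'
#' @param env_hits deduplicated environmental hit table.
#' @param calibrations calibration report from [calibrate_library()].
#' @param cfg a [filter_config()].
#' @return filtered hit table.
#' @export
filter_hits <- function(env_hits, calibrations, cfg = filter_config()) {
  if (nrow(env_hits) == 0L) return(env_hits)
  idx <- match(env_hits$model_id, calibrations$model_id)
  if (anyNA(idx)) {
    stop("filter_hits: hit references unknown model(s): ",
         paste(unique(env_hits$model_id[is.na(idx)]), collapse = ", "))
  }
  keep <- calibrations$retained[idx] &
    env_hits$evalue < cfg$evalue_max &
    env_hits$bit_score >= calibrations$score_threshold[idx]
  keep[is.na(keep)] <- FALSE
  out <- env_hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
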