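## Pollution linkage: Box-Cox z-score pooling of heterogeneous surveys,
## haversine nearest-point matching within a radius, radius sensitivity,
## Spearman correlation of hit abundance with pooled pollution, and the
## Siegel repeated-median trend fit.

EARTH_RADIUS_KM <- 6371.0088   # IUGG mean radius

#' Great-circle (haversine) distance in kilometres
#'
#' Sphere of radius 6371.0088 km; coordinates in decimal degrees.
#'
#' @param lat1,lon1,lat2,lon2 coordinates (vectorized).
#' @return distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(lat1) > 90 | abs(lat2) > 90 | abs(lon1) > 180 | abs(lon2) > 180))
    stop("haversine_km: coordinates out of range")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

#' Box-Cox transform
#'
#' @param x positive values.
#' @param lambda power parameter; `lambda = 0` is the log transform.
#' @return transformed values.
#' @export
boxcox_transform <- function(x, lambda) {
  if (any(x <= 0)) stop("boxcox_transform: non-positive input")
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

#' Maximum-likelihood Box-Cox lambda
#'
#' Maximizes the profile log-likelihood of the one-parameter power
#' transform, `-n/2 * log(sigma^2_hat(lambda)) + (lambda - 1) * sum(log x)`,
#' by bounded search on `[-5, 5]` to tolerance 1e-6.
#'
#' @param x positive values (length >= 3).
#' @param interval search interval.
#' @return the fitted lambda.
#' @export
boxcox_lambda <- function(x, interval = c(-5, 5)) {
  if (any(x <= 0)) stop("boxcox_lambda: non-positive input")
  stopifnot(length(x) >= 3)
  n <- length(x)
  slog <- sum(log(x))
  ll <- function(lam) {
    y <- boxcox_transform(x, lam)
    s2 <- mean((y - mean(y))^2)
    -n / 2 * log(s2) + (lam - 1) * slog
  }
  optimize(ll, interval = interval, maximum = TRUE, tol = 1e-6)$maximum
}

#' Profile log-likelihood of the Box-Cox transform (for diagnostics)
#'
#' @param x positive values.
#' @param lambda power parameter(s).
#' @return log-likelihood value(s).
#' @export
boxcox_loglik <- function(x, lambda) {
  n <- length(x)
  slog <- sum(log(x))
  vapply(lambda, function(lam) {
    y <- boxcox_transform(x, lam)
    -n / 2 * log(mean((y - mean(y))^2)) + (lam - 1) * slog
  }, numeric(1))
}

#' Pool pollution surveys onto a common standardized scale
#'
#' Per survey, independently: shift by `1 - min` if any value is
#' non-positive, Box-Cox transform with the fitted lambda, then z-score
#' (mean 0, sd 1 within survey). With `global_z = TRUE` the z-scoring is
#' instead done once over all transformed surveys.
#'
#' @param surveys list of data frames (`survey_id`, `lat`, `lon`, `value`),
#'   each with >= 3 points.
#' @param global_z z-score across the pooled transformed values instead of
#'   per survey.
#' @return one data frame with columns `survey_id`, `lat`, `lon`, `value`,
#'   `pooled_z`, `point_index`, plus a `"pooling"` attribute recording each
#'   survey's shift and lambda.
#' @export
pool_surveys <- function(surveys, global_z = FALSE) {
  stopifnot(length(surveys) >= 1)
  prov <- list()
  pooled <- lapply(surveys, function(sv) {
    stopifnot(nrow(sv) >= 3)
    x <- sv$value
    shift <- if (min(x) <= 0) 1 - min(x) else 0
    lam <- boxcox_lambda(x + shift)
    y <- boxcox_transform(x + shift, lam)
    if (sd(y) == 0) stop("pool_surveys: zero variance after transform in ",
                         sv$survey_id[1])
    sv$transformed <- y
    prov[[sv$survey_id[1]]] <<- c(shift = shift, lambda = lam)
    sv
  })
  out <- do.call(rbind, pooled)
  if (global_z) {
    out$pooled_z <- (out$transformed - mean(out$transformed)) /
      sd(out$transformed)
  } else {
    out$pooled_z <- unlist(lapply(split(out$transformed, out$survey_id),
                                  function(y) (y - mean(y)) / sd(y))[
                                    unique(out$survey_id)], use.names = FALSE)
  }
  out$transformed <- NULL
  out$point_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "pooling") <- prov
  out
}

#' Match each sample to its nearest pollution point within a radius
#'
#' Nearest by haversine distance; a sample is matched only if the nearest
#' point lies within `radius_km`. Exact distance ties are broken by
#' `(survey_id, point_index)` lexicographic order.
#'
#' @param samples data frame (`sample_id`, `lat`, `lon`).
#' @param points pooled point table from [pool_surveys()].
#' @param radius_km maximum matching radius, km.
#' @return data frame (`sample_id`, `point_index`, `survey_id`,
#'   `distance_km`, `pooled_z`); unmatched samples carry `NA`s.
#' @export
match_pollution <- function(samples, points, radius_km) {
  stopifnot(radius_km > 0)
  pts <- points[order(points$survey_id, points$point_index), , drop = FALSE]
  out <- lapply(seq_len(nrow(samples)), function(i) {
    d <- haversine_km(samples$lat[i], samples$lon[i], pts$lat, pts$lon)
    j <- which.min(d)    # first minimum = (survey_id, point_index) order
    if (d[j] <= radius_km) {
      data.frame(sample_id = samples$sample_id[i],
                 point_index = pts$point_index[j],
                 survey_id = pts$survey_id[j], distance_km = d[j],
                 pooled_z = pts$pooled_z[j], stringsAsFactors = FALSE)
    } else {
      data.frame(sample_id = samples$sample_id[i],
                 point_index = NA_integer_, survey_id = NA_character_,
                 distance_km = NA_real_, pooled_z = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Radius sensitivity of the pollution correlation
#'
#' For each radius: match samples to points, then Spearman-correlate matched
#' samples' hit counts with the pooled pollution z-scores.
#'
#' @param samples data frame (`sample_id`, `lat`, `lon`).
#' @param points pooled point table.
#' @param hit_counts named numeric vector sample_id -> hit count.
#' @param radii numeric vector of radii (km), length >= 2.
#' @return data frame (`radius_km`, `n_matched`, `coverage`, `rho`,
#'   `p_value`, `note`).
#' @export
radius_sensitivity <- function(samples, points, hit_counts, radii) {
  stopifnot(length(radii) >= 2)
  rows <- lapply(sort(radii), function(r) {
    m <- match_pollution(samples, points, r)
    ok <- !is.na(m$pooled_z)
    note <- ""
    rho <- p <- NA_real_
    if (sum(ok) >= 3) {
      ct <- spearman_cor(unname(hit_counts[m$sample_id[ok]]), m$pooled_z[ok])
      rho <- ct$rho
      p <- ct$p_value
    } else {
      note <- "fewer than 3 matched samples; rho omitted"
    }
    data.frame(radius_km = r, n_matched = sum(ok),
               coverage = sum(ok) / nrow(samples), rho = rho, p_value = p,
               note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Siegel repeated-median line fit
#'
#' `slope = median_i median_{j != i} (y_j - y_i) / (x_j - x_i)` (pairs with
#' equal x excluded from the inner median);
#' `intercept = median_i (y_i - slope * x_i)`. Robust with 50% breakdown.
#'
#' @param x,y numeric vectors of equal length with >= 2 distinct x.
#' @return list (`slope`, `intercept`).
#' @export
repeated_median_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (length(unique(x)) < 2) stop("repeated_median_fit: all x equal")
  n <- length(x)
  med_i <- vapply(seq_len(n), function(i) {
    dx <- x - x[i]
    ok <- dx != 0
    median((y[ok] - y[i]) / dx[ok])
  }, numeric(1))
  slope <- median(med_i)
  intercept <- median(y - slope * x)
  list(slope = slope, intercept = intercept)
}

#' Correlate matched pollution with per-sample hit counts
#'
#' Spearman correlation of hit counts against pooled pollution z-scores over
#' the matched samples, plus a repeated-median trend fit (counts on
#' pooled_z) for plotting.
#'
#' @param matches output of [match_pollution()].
#' @param hit_counts named numeric vector sample_id -> hit count.
#' @return list (`cor` — [spearman_cor()] result, `fit` —
#'   [repeated_median_fit()] result, `n_matched`).
#' @export
correlate_pollution <- function(matches, hit_counts) {
  ok <- !is.na(matches$pooled_z)
  if (sum(ok) < 3) stop("correlate_pollution: fewer than 3 matched samples")
  counts <- unname(hit_counts[matches$sample_id[ok]])
  z <- matches$pooled_z[ok]
  ct <- spearman_cor(counts, z)
  fit <- repeated_median_fit(z, counts)
  list(cor = ct, fit = fit, n_matched = sum(ok))
}

#' Join soil-type hit counts to country-level waste shares
#'
#' Country-level linkage is an exact key join on the country column (no
#' spatial matching), standardized the same way as the surveys.
#'
#' @param sample_countries data frame (`sample_id`, `country`).
#' @param country_waste data frame (`country`, `share`), share of
#'   inadequately managed plastic waste.
#' @param hit_counts named numeric vector sample_id -> hit count.
#' @return list (`cor`, `fit`, `n_matched`, `data`).
#' @export
correlate_country_waste <- function(sample_countries, country_waste,
                                    hit_counts) {
  share <- country_waste$share[match(sample_countries$country,
                                     country_waste$country)]
  ok <- !is.na(share)
  if (sum(ok) < 3) stop("correlate_country_waste: fewer than 3 matched samples")
  x <- share[ok]
  shift <- if (min(x) <= 0) 1 - min(x) else 0
  lam <- boxcox_lambda(x + shift)
  y <- boxcox_transform(x + shift, lam)
  z <- (y - mean(y)) / sd(y)
  counts <- unname(hit_counts[sample_countries$sample_id[ok]])
  list(cor = spearman_cor(counts, z), fit = repeated_median_fit(z, counts),
       n_matched = sum(ok),
       data = data.frame(sample_id = sample_countries$sample_id[ok],
                         waste_z = z, n_hits = counts,
                         stringsAsFactors = FALSE))
}
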