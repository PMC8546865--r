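test_that("haversine closed forms hold on the reference sphere", {
  expect_equal(haversine_km(10, 20, 10, 20), 0)
  R <- 6371.0088
  expect_equal(haversine_km(0, 0, 0, 90), pi * R / 2, tolerance = 1e-6)
  expect_equal(signif(haversine_km(0, 0, 0, 90), 4), signif(10007.54, 4))
  expect_equal(haversine_km(0, 0, 0, 1), pi * R / 180, tolerance = 1e-6)
  expect_equal(signif(haversine_km(0, 0, 0, 1), 4), signif(111.195, 4))
  ## symmetric, agrees with the longhand oracle
  set.seed(25)
  la <- runif(5, -80, 80); lo <- runif(5, -170, 170)
  lb <- runif(5, -80, 80); lo2 <- runif(5, -170, 170)
  expect_equal(haversine_km(la, lo, lb, lo2), haversine_km(lb, lo2, la, lo))
  expect_equal(haversine_km(la, lo, lb, lo2),
               oracle_haversine(la, lo, lb, lo2), tolerance = 1e-6)
  expect_error(haversine_km(95, 0, 0, 0), "range")
})

test_that("Box-Cox lambda is recovered for log and identity transforms", {
  set.seed(27)
  x_lognorm <- exp(rnorm(500))
  expect_lt(abs(boxcox_lambda(x_lognorm) - 0), 0.1)
  set.seed(28)
  x_norm <- rnorm(500) + 10
  expect_lt(abs(boxcox_lambda(x_norm) - 1), 0.25)
  ## optimality: likelihood at the optimum beats every grid point
  lam_hat <- boxcox_lambda(x_lognorm)
  grid <- seq(-5, 5, by = 0.01)
  expect_gte(boxcox_loglik(x_lognorm, lam_hat) + 1e-8,
             max(boxcox_loglik(x_lognorm, grid)))
  expect_error(boxcox_lambda(c(-1, 2, 3)), "non-positive")
})

test_that("survey pooling standardizes each survey and preserves rank order", {
  set.seed(29)
  base <- exp(rnorm(20))
  s1 <- data.frame(survey_id = "A", lat = 1:20, lon = 1:20, value = base)
  s2 <- data.frame(survey_id = "B", lat = 1:20, lon = 1:20,
                   value = 1000 * base)
  pooled <- pool_surveys(list(s1, s2))
  for (s in c("A", "B")) {
    z <- pooled$pooled_z[pooled$survey_id == s]
    expect_lt(abs(mean(z)), 1e-10)
    expect_equal(sd(z), 1, tolerance = 1e-10)
  }
  ## same field on scales x1 and x1000: pooled z-scores agree in rank order
  expect_equal(rank(pooled$pooled_z[pooled$survey_id == "A"]),
               rank(pooled$pooled_z[pooled$survey_id == "B"]))
  ## and (power-law rescaling, log-optimal lambda) nearly in value
  expect_equal(pooled$pooled_z[pooled$survey_id == "A"],
               pooled$pooled_z[pooled$survey_id == "B"], tolerance = 1e-4)
  ## single survey equals plain Box-Cox + z-score
  one <- pool_surveys(list(s1))
  lam <- boxcox_lambda(base)
  y <- boxcox_transform(base, lam)
  expect_equal(one$pooled_z, (y - mean(y)) / sd(y))
  ## shift handling for non-positive values
  s3 <- data.frame(survey_id = "C", lat = 1:5, lon = 1:5,
                   value = c(-2, 0, 1, 3, 8))
  p3 <- pool_surveys(list(s3))
  expect_equal(unname(attr(p3, "pooling")$C["shift"]), 3)
})

test_that("nearest-point matching respects the radius with deterministic ties", {
  pts <- data.frame(survey_id = c("A", "A"), lat = c(0, 0), lon = c(1, 5),
                    value = c(1, 2), pooled_z = c(0.1, 0.2),
                    point_index = 1:2)
  smp <- data.frame(sample_id = "S1", lat = 0, lon = 0)
  m <- match_pollution(smp, pts, 400)
  expect_equal(m$point_index, 1)
  expect_equal(m$distance_km, haversine_km(0, 0, 0, 1))
  ## radius 100: nearest point is 111.2 km away, unmatched
  m100 <- match_pollution(smp, pts, 100)
  expect_true(is.na(m100$point_index))
  ## exact tie broken by (survey_id, point_index)
  tie <- data.frame(survey_id = c("B", "A"), lat = c(0, 0), lon = c(-1, 1),
                    value = 1:2, pooled_z = c(1, 2), point_index = c(1, 2))
  mt <- match_pollution(smp, tie, 400)
  expect_equal(mt$survey_id, "A")

  ## 50 x 50 seeded instance vs the exhaustive pairwise oracle
  set.seed(33)
  samples <- data.frame(sample_id = sprintf("S%02d", 1:50),
                        lat = runif(50, -60, 60), lon = runif(50, -179, 179))
  points <- data.frame(survey_id = sample(LETTERS[1:4], 50, TRUE),
                       lat = runif(50, -60, 60), lon = runif(50, -179, 179),
                       value = runif(50), pooled_z = rnorm(50),
                       point_index = 1:50)
  got <- match_pollution(samples, points, 2000)
  D <- outer(seq_len(50), seq_len(50), function(i, j)
    oracle_haversine(samples$lat[i], samples$lon[i],
                     points$lat[j], points$lon[j]))
  for (i in seq_len(50)) {
    j <- which.min(D[i, ])
    if (D[i, j] <= 2000) {
      expect_equal(got$point_index[i], points$point_index[j])
      expect_equal(got$distance_km[i], D[i, j], tolerance = 1e-6)
      expect_lte(got$distance_km[i], 2000)
    } else {
      expect_true(is.na(got$point_index[i]))
    }
  }
  ## idempotent and order-invariant
  expect_equal(match_pollution(samples, points[sample(50), ], 2000), got)
})

test_that("radius sensitivity is monotone in coverage and reaches everything", {
  set.seed(35)
  samples <- data.frame(sample_id = sprintf("S%02d", 1:30),
                        lat = runif(30, -60, 60), lon = runif(30, -179, 179))
  points <- data.frame(survey_id = "A", lat = runif(30, -60, 60),
                       lon = runif(30, -179, 179), value = runif(30),
                       pooled_z = rnorm(30), point_index = 1:30)
  counts <- setNames(rpois(30, 20), samples$sample_id)
  half_earth <- pi * 6371.0088    # half circumference: nothing is farther
  rs <- radius_sensitivity(samples, points, counts,
                           c(200, 1000, 5000, half_earth))
  expect_true(all(diff(rs$n_matched) >= 0))
  expect_equal(rs$n_matched[nrow(rs)], 30)
  expect_equal(rs$coverage[nrow(rs)], 1)
})

test_that("repeated-median fit is exact on lines and robust to outliers", {
  fit <- repeated_median_fit(1:5, 2 * (1:5) + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  ## one gross outlier does not move the slope
  x6 <- c(1:5, 6); y6 <- c(2 * (1:5) + 1, 500)
  expect_equal(repeated_median_fit(x6, y6)$slope, 2)
  ## 30 seeded points: exactly equals the O(n^2) double-median oracle
  set.seed(37)
  x <- rnorm(30); y <- 1.5 * x + rnorm(30)
  got <- repeated_median_fit(x, y)
  med_i <- vapply(1:30, function(i) {
    sl <- (y[-i] - y[i]) / (x[-i] - x[i])
    median(sl[is.finite(sl)])
  }, numeric(1))
  slope_o <- median(med_i)
  expect_identical(got$slope, slope_o)
  expect_identical(got$intercept, median(y - slope_o * x))
  ## order invariance
  perm <- sample(30)
  expect_equal(repeated_median_fit(x[perm], y[perm])$slope, got$slope)
  ## breakdown: corrupting 40% of y leaves the slope in the clean envelope
  yc <- y; yc[1:12] <- yc[1:12] + 1000
  expect_lt(abs(repeated_median_fit(x, yc)$slope - got$slope),
            diff(range(med_i)))
  expect_error(repeated_median_fit(rep(1, 5), 1:5), "all x equal")
})

test_that("pollution correlation recovers monotone and null couplings", {
  m <- data.frame(sample_id = sprintf("S%d", 1:10), point_index = 1:10,
                  survey_id = "A", distance_km = 10,
                  pooled_z = seq(-2, 2, length.out = 10))
  counts <- setNames(1:10, m$sample_id)
  cp <- correlate_pollution(m, counts)
  expect_equal(cp$cor$rho, 1)
  ## counts independent of pollution: |rho| stays small at n = 60
  set.seed(39)
  m60 <- data.frame(sample_id = sprintf("S%02d", 1:60), point_index = 1:60,
                    survey_id = "A", distance_km = 10, pooled_z = rnorm(60))
  c60 <- setNames(rpois(60, 20), m60$sample_id)
  expect_lt(abs(correlate_pollution(m60, c60)$cor$rho), 0.3)
  expect_error(correlate_pollution(m60[1:2, ], c60), "fewer than 3")
})

test_that("country-level linkage joins on exact keys and standardizes shares", {
  sc <- data.frame(sample_id = sprintf("S%d", 1:6),
                   country = c("A", "A", "B", "C", "D", "Zz"))
  cw <- data.frame(country = c("A", "B", "C", "D"),
                   share = c(2, 10, 25, 60))
  counts <- setNames(c(1, 2, 5, 9, 20, 3), sc$sample_id)
  res <- correlate_country_waste(sc, cw, counts)
  expect_equal(res$n_matched, 5)      # 'Zz' has no waste record
  expect_gt(res$cor$rho, 0.8)         # counts increase with share here
})
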