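test_that("window enumeration produces (T-1)(T-2)/2 windows of length >= 3", {
  for (T in c(3, 5, 8, 12)) {
    ser <- data.frame(day = seq(0, by = 0.5, length.out = T),
                      N = exp(rnorm(T)))
    fits <- enumerate_windows(ser)
    expect_equal(nrow(fits), (T - 1) * (T - 2) / 2)
    expect_true(all(fits$n_points >= 3))
    expect_true(all(fits$n_points <= T))
  }
  # zeros are unusable and break runs: 4 usable points split 2|2 -> none
  ser0 <- data.frame(day = 0:4, N = c(1, 2, 0, 3, 4))
  expect_equal(nrow(enumerate_windows(ser0)), 0)
})

test_that("noiseless exponential gives exact slope with p = 0, r2 = 1", {
  ser <- data.frame(day = seq(0, 5, 0.5), N = exp(0.5 * seq(0, 5, 0.5)))
  fits <- enumerate_windows(ser)
  expect_equal(fits$slope, rep(0.5, nrow(fits)))
  expect_true(all(fits$p_slope == 0))
  expect_true(all(fits$r2 == 1))
})

test_that("window fits agree with lm() to numerical precision", {
  for (seed in 1:20) {
    ser <- random_series(sample(5:12, 1), seed)
    fits <- enumerate_windows(ser)
    if (!nrow(fits)) next
    i <- sample(nrow(fits), 1)
    f <- fits[i, ]
    idx <- f$start_idx:f$end_idx
    m <- summary(lm(log(N) ~ day, ser[idx, ]))
    expect_equal(f$slope, m$coefficients[2, 1], tolerance = 1e-9)
    expect_equal(f$intercept, m$coefficients[1, 1], tolerance = 1e-9)
    expect_equal(f$p_slope, m$coefficients[2, 4], tolerance = 1e-9)
    expect_equal(f$r2, m$r.squared, tolerance = 1e-9)
  }
})

test_that("best-fit selection takes minimum p with deterministic tie-breaks", {
  fits <- data.frame(start_idx = 1:3, end_idx = 4:6,
                     start_day = c(0, 1, 2), end_day = c(3, 4, 5),
                     slope = c(0.5, 0.4, 0.3), intercept = 0,
                     p_slope = c(0.2, 0.01, 0.03), r2 = 1, n_points = 4L)
  expect_equal(select_best(fits, "positive")$p_slope, 0.01)
  fits$p_slope <- c(0.9, 0.6, 0.051)
  expect_null(select_best(fits, "positive"))
  # tie: longer window wins, then earlier start
  fits2 <- data.frame(start_idx = c(1, 1, 2), end_idx = c(3, 4, 5),
                      start_day = c(0, 0, 1), end_day = c(2, 3, 4),
                      slope = 0.5, intercept = 0, p_slope = 0.01, r2 = 1,
                      n_points = c(3L, 4L, 4L))
  expect_equal(select_best(fits2, "positive")$start_day, 0)
  expect_equal(select_best(fits2, "positive")$n_points, 4L)
  # sign filter
  fits$p_slope <- 0.001; fits$slope <- c(-1, 1, -0.5)
  expect_equal(select_best(fits, "negative")$slope, -1)
})

test_that("selection matches an independent brute-force oracle", {
  n_hit <- 0
  for (seed in 1:200) {
    ser <- random_series(sample(6:12, 1), seed)
    mine <- select_best(enumerate_windows(ser), "positive", 0.05)
    oracle <- brute_force_best(ser, "positive", 0.05)
    if (is.null(oracle)) {
      expect_null(mine)
    } else {
      n_hit <- n_hit + 1
      expect_equal(mine$start_idx, oracle$start_idx)
      expect_equal(mine$end_idx, oracle$end_idx)
      expect_equal(mine$slope, oracle$slope, tolerance = 1e-8)
    }
  }
  expect_gt(n_hit, 30)    # the comparison actually exercised discoveries
})

test_that("noiseless planted dynamics are recovered exactly", {
  tr <- grower_truth(N0 = 1, mu = 0.6, t_lag = 2, t_growth_end = 5,
                     d = 0.25, t_death_start = 8, t_death_end = 14)
  ser <- noiseless_series(tr)
  est <- estimate_dynamics(ser, calibration = 0.05)
  g <- est$growth
  expect_equal(g$mu, 0.6)
  expect_equal(g$lag, 2.0)
  expect_equal(g$duration, 3.0)
  expect_equal(g$delta_Ng, exp(0.6 * 3) - 1)
  expect_equal(g$generation_time * g$mu, log(2))
  d <- est$death
  expect_equal(d$d, 0.25)
  expect_equal(d$start_day, 8)
  expect_equal(d$halving_time_h, log(2) / 0.25 * 24)
  # the detected death window ends at the last sampled day inside the
  # planted decay (day 13 on this schedule), so the loss is measured there
  expect_equal(d$end_day, 13)
  expect_equal(d$delta_Nd, exp(1.8) * (1 - exp(-0.25 * 5)))
})

test_that("delta_Ng is invariant to flat padding and replicate relabeling", {
  tr <- grower_truth()
  ser <- noiseless_series(tr, days = seq(0, 10, 0.5))
  g1 <- estimate_dynamics(ser, 0.05)$growth
  ser2 <- ser; ser2$replicate <- 99L
  g2 <- estimate_dynamics(ser2, 0.05)$growth
  expect_equal(g2$delta_Ng, g1$delta_Ng)
  # extra flat plateau points beyond the selected window
  ser3 <- noiseless_series(tr, days = c(seq(0, 10, 0.5), 12:20))
  g3 <- estimate_dynamics(ser3, 0.05)$growth
  expect_equal(g3$delta_Ng, g1$delta_Ng)
  expect_equal(g3[c("mu", "lag", "end_day")], g1[c("mu", "lag", "end_day")])
})

test_that("FDR calibration is bounded, monotone and deterministic", {
  truth <- rbind(fdr_mixture_truth(30, 70, seed = 2))
  ser <- series_from_truth(truth, seed = 3)
  ser <- ser[ser$informative, ]
  cal <- calibrate_fdr(ser, n_null = 150, seed = 4)
  expect_s3_class(cal, "null_calibration")
  expect_true(cal$p_star > 0 && cal$p_star <= 0.05)
  cal2 <- calibrate_fdr(ser, n_null = 150, seed = 4)
  expect_equal(cal$p_star, cal2$p_star)
  strict <- calibrate_fdr(ser, n_null = 150, target_fdr = 0.01, seed = 4)
  expect_lte(strict$p_star, cal$p_star)
  expect_error(calibrate_fdr(ser, n_null = 50), "100")
})

test_that("flat null series yield few discoveries at the calibrated threshold", {
  ser <- series_from_truth(flat_truth(150, N0 = 1), seed = 6)
  ser <- ser[ser$informative, ]
  cal <- suppressWarnings(calibrate_fdr(ser, n_null = 200, seed = 7))
  est <- suppressWarnings(estimate_dynamics(ser, cal))
  n_series <- length(unique(ser$asv_id))
  expect_lte(nrow(est$growth), 0.05 * n_series + 2 * sqrt(0.05 * n_series))
})

test_that("replicate averaging is per-parameter", {
  g <- data.frame(asv_id = "a", soil = "m", replicate = 1:2,
                  mu = c(0.4, 0.6), generation_time = log(2) / c(0.4, 0.6),
                  lag = c(1, 2), end_day = c(4, 5), duration = c(3, 3),
                  N_start = 1, N_end = 2, delta_Ng = 1, p_slope = 0.001,
                  r2 = 0.9, n_points = 5L)
  avg <- average_replicates(g)
  expect_equal(avg$mu, 0.5)
  expect_equal(avg$n_replicates, 2L)
  # mean of generation times, not ln2 / mean(mu) (Jensen)
  expect_equal(avg$generation_time, mean(log(2) / c(0.4, 0.6)))
  expect_gt(avg$generation_time, log(2) / avg$mu)
  one <- average_replicates(g[1, ])
  expect_equal(one$mu, 0.4)
  expect_equal(one$n_replicates, 1L)
})

test_that("grew-then-died requires death to start after growth ends", {
  g <- data.frame(asv_id = c("a", "b", "c"), soil = "m", replicate = 1L,
                  end_day = c(5, 5, 5))
  d <- data.frame(asv_id = c("a", "b"), soil = "m", replicate = 1L,
                  start_day = c(6, 4))
  out <- grew_then_died(g, d)
  expect_equal(out$n_grew, 3L)
  expect_equal(out$n_grew_then_died, 1L)   # only "a": 6 >= 5; "b" overlaps
  expect_equal(out$proportion, 1 / 3)
})

test_that("grew-then-died recovers a planted proportion", {
  # 20 growers, 10 of them with a death phase after growth
  tg <- do.call(rbind, lapply(1:20, function(i)
    grower_truth(asv_id = sprintf("g%02d", i), N0 = 2, mu = 0.8,
                 t_lag = 1.5, t_growth_end = 5,
                 d = if (i <= 10) 0.4 else 0,
                 t_death_start = if (i <= 10) 7 else Inf,
                 t_death_end = if (i <= 10) 14 else Inf)))
  ser <- series_from_truth(tg, seed = 12, depth = 5e4)
  est <- estimate_dynamics(ser[ser$informative, ], 1e-4)
  out <- grew_then_died(est$growth, est$death)
  expect_equal(out$proportion, 0.5, tolerance = 0.2)
})

test_that("detection power rises with planted effect size", {
  prob <- vapply(c(0.35, 0.6, 1.0), function(mu) {
    tg <- do.call(rbind, lapply(1:30, function(i)
      grower_truth(asv_id = sprintf("g%02d", i), N0 = 0.3, mu = mu,
                   t_lag = 2, t_growth_end = 5)))
    tg <- rbind(tg, flat_truth(30))
    ser <- series_from_truth(tg, seed = 31, depth = 1e4)
    est <- estimate_dynamics(ser[ser$informative, ], 1e-4)
    sum(grepl("^g", est$growth$asv_id)) / 30
  }, numeric(1))
  expect_true(all(diff(prob) >= 0))
  expect_gt(prob[3], 0.8)
})
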