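# Fixtures are built in code; nothing is stored on disk.

# one-row truth table for a grower (no death unless given)
grower_truth <- function(asv_id = "g1", N0 = 1, mu = 0.6, t_lag = 2,
                         t_growth_end = 5, d = 0, t_death_start = Inf,
                         t_death_end = Inf, yield_c = 1, rrn = 1) {
  data.frame(asv_id = asv_id, strategy = "C", N0 = N0, mu = mu,
             t_lag = t_lag, t_growth_end = t_growth_end, d = d,
             t_death_start = t_death_start, t_death_end = t_death_end,
             yield_c = yield_c, rrn = rrn, litter = TRUE)
}

flat_truth <- function(n, N0 = 0.5, prefix = "n") {
  data.frame(asv_id = sprintf("%s%03d", prefix, seq_len(n)), strategy = "null",
             N0 = N0, mu = 0, t_lag = 0, t_growth_end = 0, d = 0,
             t_death_start = Inf, t_death_end = Inf, yield_c = 0, rrn = 1,
             litter = FALSE)
}

# mixed-community truth for FDR evaluation: growth responders are a
# minority that starts rare and blooms ~10x; null taxa carry the
# established biomass, so total community mass roughly doubles.
fdr_mixture_truth <- function(n_grow = 200, n_null = 800, seed = 1) {
  set.seed(seed)
  tg <- data.frame(
    asv_id = sprintf("g%03d", seq_len(n_grow)), strategy = "C",
    N0 = exp(runif(n_grow, log(0.1), log(0.4))),
    mu = runif(n_grow, 0.4, 1.0),
    t_lag = runif(n_grow, 1, 6),
    d = 0, t_death_start = Inf, t_death_end = Inf,
    yield_c = 1, rrn = 1, litter = TRUE)
  tg$t_growth_end <- tg$t_lag + runif(n_grow, 2, 5)
  tn <- flat_truth(n_null)
  set.seed(seed + 1)
  tn$N0 <- exp(runif(n_null, log(0.2), log(2)))
  rbind(tg[, names(tn)], tn)
}

# simulate counts at fixed depth (no depth variation) and build series
series_from_truth <- function(truth, seed, replicates = 1L, depth = 1e4,
                              design = NULL) {
  if (is.null(design))
    design <- default_design(replicates = replicates, depth_mean = depth,
                             depth_sd = depth * 1e-9, depth_min = depth)
  cs <- sample_counts(truth, design, seed = seed)
  quantify(cs$counts, cs$metadata, NULL, do_rarefy = FALSE)
}

# a noiseless series data.frame on a day grid
noiseless_series <- function(truth, days = default_design()$days) {
  data.frame(asv_id = truth$asv_id[1], soil = "s", replicate = 1L,
             day = days, N = trajectory(truth, days)[1, ])
}

# independent brute-force re-implementation of window fitting + selection
# via lm(): fits every window explicitly and sorts candidates.
brute_force_best <- function(series, sign = "positive", p_max = 0.05,
                             min_len = 3L) {
  usable <- is.finite(series$N) & series$N > 0
  r <- rle(usable)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  cand <- list()
  for (k in which(r$values & r$lengths >= min_len)) {
    for (i in starts[k]:(ends[k] - min_len + 1L)) {
      for (j in (i + min_len - 1L):ends[k]) {
        d <- series$day[i:j]; y <- log(series$N[i:j])
        fit <- summary(lm(y ~ d))
        slope <- fit$coefficients[2, 1]
        p <- fit$coefficients[2, 4]
        if (!is.finite(slope)) next
        keep <- if (sign == "positive") slope > 1e-9 else slope < -1e-9
        # lm reports p = NA for an exact fit; an exact sloped fit is p = 0
        if (is.na(p) && fit$sigma < 1e-8) p <- 0
        if (keep && !is.na(p) && p < p_max)
          cand[[length(cand) + 1L]] <- data.frame(
            start_idx = i, end_idx = j, slope = slope, p_slope = p,
            n_points = j - i + 1L, start_day = series$day[i])
      }
    }
  }
  if (!length(cand)) return(NULL)
  cand <- do.call(rbind, cand)
  cand[order(cand$p_slope, -cand$n_points, cand$start_day)[1], , drop = FALSE]
}

# random series with a mix of flat, trending and zero-holed shapes
random_series <- function(len, seed) {
  set.seed(seed)
  day <- sort(sample(seq(0, 15, by = 0.5), len))
  kind <- sample(3, 1)
  N <- switch(kind,
              exp(rnorm(len, 0, 0.5)),
              exp(0.4 * day + rnorm(len, 0, 0.3)),
              exp(-0.3 * day + rnorm(len, 0, 0.3)))
  if (runif(1) < 0.3) N[sample(len, 1)] <- 0
  data.frame(asv_id = "r", soil = "s", replicate = 1L, day = day, N = N)
}
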