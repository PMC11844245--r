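# Growth/death detection by exhaustive window regression on
# ln(normalized abundance), with simulation-based FDR calibration.
#
# The window fitter is written in closed form on prefix sums rather than
# through lm(): a 30-point series implies several hundred windows and the
# null calibration refits thousands of series.

# all-window OLS for one contiguous run of usable points.
# x: days, y: ln N. Returns data.frame of fits with local indices.
fit_run <- function(x, y, min_len = 3L) {
  T <- length(x)
  if (T < min_len) return(NULL)
  cx <- c(0, cumsum(x));  cy <- c(0, cumsum(y))
  cxx <- c(0, cumsum(x * x)); cxy <- c(0, cumsum(x * y)); cyy <- c(0, cumsum(y * y))
  pair <- which(outer(seq_len(T), seq_len(T),
                      function(i, j) j - i >= min_len - 1L), arr.ind = TRUE)
  i <- pair[, 1]; j <- pair[, 2]
  n <- j - i + 1
  Sx <- cx[j + 1] - cx[i];  Sy <- cy[j + 1] - cy[i]
  Sxx <- cxx[j + 1] - cxx[i]; Sxy <- cxy[j + 1] - cxy[i]; Syy <- cyy[j + 1] - cyy[i]
  sxx <- Sxx - Sx^2 / n
  sxy <- Sxy - Sx * Sy / n
  syy <- Syy - Sy^2 / n
  slope <- sxy / sxx
  intercept <- (Sy - slope * Sx) / n
  sse <- pmax(syy - slope * sxy, 0)
  # residuals at floating-point rounding scale are an exact fit
  sse[sse <= 1e-10 * syy] <- 0
  df <- n - 2
  se <- sqrt(sse / df / sxx)
  # a perfect fit (sse = 0) of a genuinely sloped line has p = 0; a flat
  # window whose slope is only floating-point jitter must not
  flat <- abs(slope) < 1e-9
  slope[flat] <- 0
  tstat <- ifelse(se > 0, slope / se,
                  ifelse(flat, 0, sign(slope) * Inf))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  r2 <- ifelse(syy > 0, 1 - sse / syy, NA_real_)
  data.frame(start_idx = i, end_idx = j,
             start_day = x[i], end_day = x[j],
             slope = slope, intercept = intercept,
             p_slope = p, r2 = r2, n_points = n)
}

#' Fit every window of consecutive usable time points in one series
#'
#' Natural-log-transforms the abundances and fits an OLS line over every
#' window of at least `min_len` consecutive usable points (N > 0), over
#' every maximal run of usable points. Zero abundances are unusable under
#' the log transform and break runs; no pseudo-count is added.
#' Regression uses the actual (non-uniform) day values, so the slope is
#' the specific rate in day^-1.
#'
#' @param series data.frame with columns `day` (strictly increasing) and
#'   `N` (normalized abundance) for a single series.
#' @param min_len minimum window length (default 3).
#' @return data.frame of window fits (start/end index and day, slope,
#'   intercept, two-sided slope p-value, r2, n_points); zero rows if the
#'   series has fewer than `min_len` usable points anywhere.
#' @export
enumerate_windows <- function(series, min_len = 3L) {
  day <- series$day
  if (is.unsorted(day, strictly = TRUE)) stop("days must be strictly increasing")
  usable <- is.finite(series$N) & series$N > 0
  out <- list()
  r <- rle(usable)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values & r$lengths >= min_len)) {
    idx <- starts[k]:ends[k]
    fits <- fit_run(day[idx], log(series$N[idx]), min_len)
    if (!is.null(fits)) {
      fits$start_idx <- fits$start_idx + starts[k] - 1L
      fits$end_idx <- fits$end_idx + starts[k] - 1L
      out[[length(out) + 1L]] <- fits
    }
  }
  if (!length(out))
    return(data.frame(start_idx = integer(), end_idx = integer(),
                      start_day = numeric(), end_day = numeric(),
                      slope = numeric(), intercept = numeric(),
                      p_slope = numeric(), r2 = numeric(),
                      n_points = integer()))
  do.call(rbind, out)
}

#' Select the single best-supported window fit
#'
#' Among fits whose slope has the requested sign and whose slope p-value
#' is below `p_max`, returns the fit with the smallest p-value. Ties are
#' broken deterministically: longer window first, then earlier start day.
#'
#' @param fits data.frame from [enumerate_windows()].
#' @param sign `"positive"` for growth, `"negative"` for death.
#' @param p_max recording threshold on the slope p-value (default 0.05).
#' @return a one-row data.frame, or NULL if no fit qualifies.
#' @export
select_best <- function(fits, sign = c("positive", "negative"), p_max = 0.05) {
  sign <- match.arg(sign)
  ok <- if (sign == "positive") fits$slope > 0 else fits$slope < 0
  ok <- ok & fits$p_slope < p_max
  if (!any(ok)) return(NULL)
  fits <- fits[ok, , drop = FALSE]
  ord <- order(fits$p_slope, -fits$n_points, fits$start_day)
  fits[ord[1], , drop = FALSE]
}

split_series <- function(series) {
  key <- paste(series$asv_id, series$soil, series$replicate, sep = "\r")
  split(series, factor(key, levels = unique(key)))
}

best_p_one <- function(s, min_len, p_max, sign = "positive") {
  fits <- enumerate_windows(s, min_len)
  b <- select_best(fits, sign, p_max)
  if (is.null(b)) NA_real_ else b$p_slope
}

#' Calibrate the FDR-controlling p-value threshold by null simulation
#'
#' Builds null series and runs the identical detection algorithm on them
#' to estimate, for each candidate threshold p, the expected fraction of
#' discoveries that are false. The default null permutes each sampled
#' real series' abundances across its own time points, preserving the
#' marginal distribution and the sampling grid while destroying temporal
#' order; `method = "flat-noise"` instead draws iid lognormal values with
#' the series' own log-mean and log-SD. The plug-in estimate is
#' \deqn{\widehat{FDR}(p) = \frac{\hat F_0(p) \cdot n_{series}}{\#\{best\ p \le p\}}}
#' where \eqn{\hat F_0} is the null ECDF of best p-values, and the
#' calibrated threshold is the largest \eqn{p \le p_{max}} with estimated
#' FDR at or below `target_fdr`.
#'
#' @param series long series data.frame (asv_id, soil, replicate, day, N).
#' @param n_null number of null series to simulate (>= 100).
#' @param target_fdr target false discovery rate (default 0.05).
#' @param p_max recording threshold of the detector (default 0.05).
#' @param min_len minimum window length.
#' @param seed integer seed; deterministic given the seed.
#' @param method null construction, `"permute"` or `"flat-noise"`.
#' @return object of class `null_calibration`: method, n_null,
#'   `null_best_p`, `real_best_p`, `p_star`, `target_fdr`, `n_series`.
#'   `p_star` is NA (with a warning) if no threshold qualifies.
#' @export
calibrate_fdr <- function(series, n_null = 1000L, target_fdr = 0.05,
                          p_max = 0.05, min_len = 3L, seed = 1,
                          method = c("permute", "flat-noise")) {
  method <- match.arg(method)
  if (n_null < 100) stop("n_null must be at least 100")
  set.seed(seed)
  groups <- split_series(series)
  real_best <- vapply(groups, best_p_one, numeric(1),
                      min_len = min_len, p_max = p_max)
  pick <- sample.int(length(groups), n_null, replace = TRUE)
  null_best <- vapply(pick, function(g) {
    s <- groups[[g]]
    usable <- is.finite(s$N) & s$N > 0
    if (method == "permute") {
      s$N <- sample(s$N)
    } else {
      ln <- log(s$N[usable])
      if (length(ln) < 2) return(NA_real_)
      s$N <- exp(rnorm(nrow(s), mean(ln), max(sd(ln), 1e-8)))
    }
    best_p_one(s, min_len, p_max)
  }, numeric(1))
  n_series <- length(groups)
  disc_p <- sort(real_best[!is.na(real_best)])
  cal <- structure(list(method = method, n_null = n_null,
                        null_best_p = null_best, real_best_p = real_best,
                        target_fdr = target_fdr, p_max = p_max,
                        n_series = n_series, p_star = NA_real_),
                   class = "null_calibration")
  if (!length(disc_p)) {
    warning("no discoveries at p_max; p_star undefined")
    return(cal)
  }
  est_fdr <- vapply(disc_p, function(p) {
    f0 <- sum(null_best <= p, na.rm = TRUE) / n_null
    f0 * n_series / sum(disc_p <= p)
  }, numeric(1))
  ok <- est_fdr <= target_fdr
  if (!any(ok)) {
    warning("no threshold achieves the target FDR; p_star undefined")
    return(cal)
  }
  cal$p_star <- max(disc_p[ok])
  cal$est_fdr_at_p_star <- est_fdr[which(disc_p == cal$p_star)[1]]
  cal
}

#' @export
print.null_calibration <- function(x, ...) {
  cat("Null calibration (", x$method, "), ", x$n_null, " null series\n",
      "  series tested: ", x$n_series, "\n",
      "  target FDR:    ", x$target_fdr, "\n",
      "  p_star:        ", format(x$p_star), "\n", sep = "")
  invisible(x)
}

window_to_growth <- function(b, id) {
  N_start <- exp(b$intercept + b$slope * b$start_day)
  N_end <- exp(b$intercept + b$slope * b$end_day)
  data.frame(id, mu = b$slope, generation_time = log(2) / b$slope,
             lag = b$start_day, end_day = b$end_day,
             duration = b$end_day - b$start_day,
             N_start = N_start, N_end = N_end,
             delta_Ng = N_end - N_start,
             p_slope = b$p_slope, r2 = b$r2, n_points = b$n_points)
}

window_to_death <- function(b, id) {
  N_start <- exp(b$intercept + b$slope * b$start_day)
  N_end <- exp(b$intercept + b$slope * b$end_day)
  d <- -b$slope
  data.frame(id, d = d, halving_time_h = log(2) / d * 24,
             start_day = b$start_day, end_day = b$end_day,
             duration = b$end_day - b$start_day,
             N_start = N_start, N_end = N_end,
             delta_Nd = N_start - N_end,
             p_slope = b$p_slope, r2 = b$r2, n_points = b$n_points)
}

#' Estimate growth and death parameters for every series
#'
#' Runs window enumeration on each (ASV, soil, replicate) series and
#' selects the best positive-slope (growth) and negative-slope (death)
#' windows at the calibrated threshold. Growth and death are selected
#' independently and may both be present. Window-endpoint abundances are
#' taken from the fitted line, e^(intercept + slope * day), not the raw
#' observations, so `delta_Ng`/`delta_Nd` inherit the regression's noise
#' averaging.
#'
#' @param series long series data.frame.
#' @param calibration a `null_calibration`, or a numeric p-value
#'   threshold to use directly.
#' @param min_len minimum window length.
#' @return list with data.frames `growth` (mu, generation_time, lag,
#'   end_day, duration, N_start, N_end, delta_Ng, ...) and `death`
#'   (d, halving_time_h, delta_Nd, ...), one row per detected phase.
#' @export
estimate_dynamics <- function(series, calibration, min_len = 3L) {
  p_star <- if (inherits(calibration, "null_calibration"))
    calibration$p_star else calibration
  growth <- list(); death <- list()
  if (is.na(p_star)) {
    warning("p_star undefined; no estimates produced")
  } else {
    for (s in split_series(series)) {
      fits <- enumerate_windows(s, min_len)
      if (!nrow(fits)) next
      id <- data.frame(asv_id = s$asv_id[1], soil = s$soil[1],
                       replicate = s$replicate[1])
      bg <- select_best(fits, "positive", p_star)
      if (!is.null(bg)) growth[[length(growth) + 1L]] <- window_to_growth(bg, id)
      bd <- select_best(fits, "negative", p_star)
      if (!is.null(bd)) death[[length(death) + 1L]] <- window_to_death(bd, id)
    }
  }
  empty_g <- window_to_growth(
    data.frame(intercept = 0, slope = 1, start_day = 0, end_day = 1,
               p_slope = 0, r2 = 1, n_points = 3L),
    data.frame(asv_id = "", soil = "", replicate = 1L))[0, ]
  empty_d <- window_to_death(
    data.frame(intercept = 0, slope = -1, start_day = 0, end_day = 1,
               p_slope = 0, r2 = 1, n_points = 3L),
    data.frame(asv_id = "", soil = "", replicate = 1L))[0, ]
  list(growth = if (length(growth)) do.call(rbind, growth) else empty_g,
       death = if (length(death)) do.call(rbind, death) else empty_d)
}

#' Average growth/death parameters across replicates
#'
#' Arithmetic mean of every numeric parameter over the replicates in
#' which the phase was detected, per ASV and soil. Averaging is per
#' parameter: the averaged generation time is the mean of per-replicate
#' generation times, not ln2 over the mean rate.
#'
#' @param estimates a `growth` or `death` data.frame from
#'   [estimate_dynamics()].
#' @return data.frame with one row per (asv_id, soil) and `n_replicates`.
#' @export
average_replicates <- function(estimates) {
  if (!nrow(estimates)) return(cbind(estimates, n_replicates = integer(0)))
  num <- names(estimates)[vapply(estimates, is.numeric, TRUE)]
  num <- setdiff(num, "replicate")
  agg <- aggregate(estimates[num], estimates[c("asv_id", "soil")], mean)
  n <- aggregate(list(n_replicates = estimates$replicate),
                 estimates[c("asv_id", "soil")], length)
  merge(agg, n, by = c("asv_id", "soil"))
}

#' Proportion of growing taxa that subsequently died
#'
#' An (ASV, soil, replicate) counts as "grew then died" when both a
#' growth and a death estimate exist in that replicate and the death
#' window starts no earlier than the growth window ends. The proportion
#' is taken over ASV-replicates with a growth estimate, optionally within
#' groups (e.g. life-history cluster).
#'
#' @param growth,death data.frames from [estimate_dynamics()].
#' @param groups optional data.frame (asv_id, soil, group) to stratify by.
#' @return data.frame with n_grew, n_grew_then_died and proportion,
#'   overall or per group.
#' @export
grew_then_died <- function(growth, death, groups = NULL) {
  if (!nrow(growth))
    return(data.frame(n_grew = 0L, n_grew_then_died = 0L, proportion = NaN))
  key <- c("asv_id", "soil", "replicate")
  m <- merge(growth[c(key, "end_day")],
             death[c(key, "start_day")], by = key, all.x = TRUE)
  m$gtd <- !is.na(m$start_day) & m$start_day >= m$end_day
  if (is.null(groups)) {
    data.frame(n_grew = nrow(m), n_grew_then_died = sum(m$gtd),
               proportion = mean(m$gtd))
  } else {
    m <- merge(m, groups, by = intersect(names(groups), c("asv_id", "soil")))
    out <- aggregate(list(n_grew = rep(1L, nrow(m)), n_grew_then_died = m$gtd),
                     m[setdiff(names(groups), c("asv_id", "soil"))], sum)
    out$proportion <- out$n_grew_then_died / out$n_grew
    out
  }
}

#' One-call detection: calibrate then estimate
#'
#' @inheritParams calibrate_fdr
#' @return list: `growth`, `death` (as [estimate_dynamics()]) and
#'   `calibration`.
#' @export
detect_dynamics <- function(series, n_null = 1000L, target_fdr = 0.05,
                            p_max = 0.05, min_len = 3L, seed = 1,
                            method = c("permute", "flat-noise")) {
  cal <- calibrate_fdr(series, n_null, target_fdr, p_max, min_len, seed, method)
  est <- estimate_dynamics(series, cal, min_len)
  c(est, list(calibration = cal))
}
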