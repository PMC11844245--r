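# Carbon flux: CO2 mineralization rates, interval apportionment of
# growth gains, net growth efficiency, abundance-weighted generation
# time, the C:S abundance ratio, and Pearson correlations between them.

#' Impute missing CO2 measurements from neighboring flushes
#'
#' A missing value is replaced by the arithmetic mean of the immediately
#' preceding and following measurements of the same microcosm; values
#' lacking an observed neighbor on either side are left missing with a
#' warning. Imputed cells are flagged.
#'
#' @param co2 data.frame: microcosm, soil, replicate, day, co2_12, co2_13.
#' @return same data.frame with NAs filled where possible and logical
#'   columns `imputed_12`, `imputed_13`.
#' @export
impute_missing_co2 <- function(co2) {
  co2 <- co2[order(co2$microcosm, co2$day), ]
  co2$imputed_12 <- FALSE
  co2$imputed_13 <- FALSE
  for (col in c("co2_12", "co2_13")) {
    flag <- paste0("imputed_", sub("co2_", "", col))
    for (mc in unique(co2$microcosm)) {
      i <- which(co2$microcosm == mc)
      x <- co2[[col]][i]
      for (j in which(is.na(x))) {
        if (j > 1 && j < length(x) && !is.na(x[j - 1]) && !is.na(x[j + 1])) {
          co2[[col]][i[j]] <- (x[j - 1] + x[j + 1]) / 2
          co2[[flag]][i[j]] <- TRUE
        } else {
          warning("cannot impute ", col, " for ", mc, " day ",
                  co2$day[i[j]], ": missing neighbor")
        }
      }
    }
  }
  rownames(co2) <- NULL
  co2
}

#' Apportion growth gains to a time interval
#'
#' For each growing taxon the contribution over [a, b] follows the fitted
#' exponential trajectory:
#' N_start * (e^(mu (min(b, end) - lag)) - e^(mu (max(a, lag) - lag)))
#' whenever the interval overlaps the growth window, else 0. Summed over
#' intervals that tile the time course this reproduces each taxon's total
#' delta_Ng exactly (conservation).
#'
#' @param growth growth-estimate data.frame with columns mu, lag,
#'   end_day, N_start.
#' @param a,b interval bounds in days, b > a.
#' @param linear use straight-line-in-time apportionment instead of the
#'   fitted exponential (also conservative).
#' @return summed delta_Ng apportioned to the interval.
#' @export
apportion_delta_ng <- function(growth, a, b, linear = FALSE) {
  stopifnot(b > a)
  if (!nrow(growth)) return(0)
  lo <- pmax(a, growth$lag)
  hi <- pmin(b, growth$end_day)
  open <- hi > lo
  if (linear) {
    tot <- growth$N_start * (exp(growth$mu * (growth$end_day - growth$lag)) - 1)
    contrib <- ifelse(open, tot * (hi - lo) / (growth$end_day - growth$lag), 0)
  } else {
    contrib <- ifelse(open,
      growth$N_start * (exp(growth$mu * (hi - growth$lag)) -
                        exp(growth$mu * (lo - growth$lag))), 0)
  }
  sum(contrib)
}

#' Net growth efficiency of an interval
#'
#' Summed interval-apportioned growth gains of all growing taxa divided
#' by the mass of CO2 mineralized in the interval (normalized-abundance
#' units per unit CO2 mass). Intervals with zero CO2 are undefined.
#'
#' @param sum_dng interval-apportioned sum of delta_Ng.
#' @param co2_mass CO2 mass mineralized in the interval (> 0).
#' @return the ratio, or NA with a warning when co2_mass is 0.
#' @export
net_growth_efficiency <- function(sum_dng, co2_mass) {
  out <- sum_dng / co2_mass
  bad <- !is.na(co2_mass) & co2_mass == 0
  if (any(bad)) {
    warning(sum(bad), " interval(s) with zero CO2 mass skipped")
    out[bad] <- NA_real_
  }
  out
}

#' Abundance-weighted mean generation time over an interval
#'
#' Weighted mean of the generation times of taxa whose growth window
#' overlaps the interval, weighting each taxon by its fitted normalized
#' abundance at the interval midpoint (clamped into the growth window).
#'
#' @inheritParams apportion_delta_ng
#' @return weighted mean generation time (days); NA if no grower is
#'   active in the interval.
#' @export
weighted_generation_time <- function(growth, a, b) {
  stopifnot(b > a)
  if (!nrow(growth)) return(NA_real_)
  active <- growth$lag < b & growth$end_day > a
  if (!any(active)) return(NA_real_)
  g <- growth[active, , drop = FALSE]
  mid <- pmin(pmax((a + b) / 2, g$lag), g$end_day)
  w <- g$N_start * exp(g$mu * (mid - g$lag))
  sum(w * g$generation_time) / sum(w)
}

#' Competitor-to-scarcity abundance ratio at a sampled day
#'
#' Sums normalized abundance over C-labeled ASVs and divides by the sum
#' over S-labeled ASVs at the sampling day nearest to `day`; ruderals are
#' excluded by construction.
#'
#' @param labels data.frame with columns asv_id, strategy.
#' @param series long normalized series for one soil.
#' @param day target day; the nearest sampled day is used.
#' @return the ratio (NA with warning when summed S abundance is zero).
#' @export
cs_ratio <- function(labels, series, day) {
  d0 <- unique(series$day)
  d <- d0[which.min(abs(d0 - day))]
  at <- series[series$day == d, ]
  strat <- labels$strategy[match(at$asv_id, labels$asv_id)]
  cs <- sum(at$N[strat %in% "C"])
  ss <- sum(at$N[strat %in% "S"])
  if (is.na(ss) || ss == 0) {
    warning("zero scarcity-adapted abundance at day ", d, "; ratio undefined")
    return(NA_real_)
  }
  cs / ss
}

#' Pearson correlation, optionally compared between two groups
#'
#' Pearson r with a two-sided t-based p-value. When a second pair of
#' series is supplied, the two correlation coefficients are compared with
#' a Fisher r-to-z two-sample test; if the difference is non-significant
#' (at `alpha`) the groups are also pooled and a pooled correlation is
#' reported, mirroring the test-then-pool procedure.
#'
#' @param x,y paired numeric vectors (n >= 3 after NA removal).
#' @param x2,y2 optional second pair for the comparison.
#' @param alpha significance level gating the pooled estimate.
#' @return list: `r`, `p`, `n`; plus `r2`, `p2`, `n2`, `z`, `p_z`, and
#'   (when pooling is licensed) `pooled` with the combined correlation.
#' @export
correlate_pearson <- function(x, y, x2 = NULL, y2 = NULL, alpha = 0.05) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired points")
  if (var(x) == 0 || var(y) == 0) stop("zero variance; correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  out <- list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
  if (!is.null(x2)) {
    keep2 <- stats::complete.cases(x2, y2)
    x2 <- x2[keep2]; y2 <- y2[keep2]
    ct2 <- cor.test(x2, y2, method = "pearson")
    out$r2 <- unname(ct2$estimate); out$p2 <- ct2$p.value; out$n2 <- length(x2)
    z <- (atanh(out$r) - atanh(out$r2)) /
      sqrt(1 / (out$n - 3) + 1 / (out$n2 - 3))
    out$z <- z
    out$p_z <- 2 * pnorm(-abs(z))
    if (out$p_z > alpha) {
      pc <- cor.test(c(x, x2), c(y, y2), method = "pearson")
      out$pooled <- list(r = unname(pc$estimate), p = pc$p.value,
                         n = out$n + out$n2)
    }
  }
  out
}

#' Build the per-soil, per-interval carbon flux table
#'
#' Imputes missing CO2, averages microcosm CO2 within soil per flushing
#' interval, apportions growth gains to intervals, and derives the
#' mineralization rate, net growth efficiency, abundance-weighted
#' generation time, and (when strategy labels are given) the C:S ratio.
#' Intervals whose CO2 could not be imputed are dropped with a warning.
#'
#' @param co2 CO2 table (microcosm, soil, replicate, day, co2_12, co2_13).
#' @param growth_avg replicate-averaged growth estimates (all soils).
#' @param labels optional data.frame (asv_id, soil, strategy) for C:S.
#' @param series optional long series (needed for C:S).
#' @param linear passed to [apportion_delta_ng()].
#' @return data.frame: soil, t_a, t_b, co2_mass, mineralization_rate,
#'   sum_dng, nge, weighted_generation_time, cs_ratio.
#' @export
flux_series <- function(co2, growth_avg, labels = NULL, series = NULL,
                        linear = FALSE) {
  co2 <- impute_missing_co2(co2)
  out <- list()
  for (s in unique(co2$soil)) {
    cs <- co2[co2$soil == s, ]
    g <- growth_avg[growth_avg$soil == s, , drop = FALSE]
    days <- sort(unique(cs$day))
    tot <- cs$co2_12 + cs$co2_13
    mass <- tapply(tot, factor(cs$day, levels = days), mean)
    miss <- is.na(mass)
    if (any(miss)) {
      warning("dropping ", sum(miss), " interval(s) with unimputable CO2 in ", s)
      days <- days[!miss]; mass <- mass[!miss]
    }
    t_a <- c(0, head(days, -1))
    rows <- data.frame(soil = s, t_a = t_a, t_b = days,
                       co2_mass = as.numeric(mass))
    rows$mineralization_rate <- rows$co2_mass / (rows$t_b - rows$t_a)
    rows$sum_dng <- mapply(function(a, b) apportion_delta_ng(g, a, b, linear),
                           rows$t_a, rows$t_b)
    rows$nge <- net_growth_efficiency(rows$sum_dng, rows$co2_mass)
    rows$weighted_generation_time <-
      mapply(function(a, b) weighted_generation_time(g, a, b),
             rows$t_a, rows$t_b)
    if (!is.null(labels) && !is.null(series)) {
      lab_s <- labels[labels$soil == s, , drop = FALSE]
      ser_s <- series[series$soil == s, , drop = FALSE]
      rows$cs_ratio <- vapply(
        (rows$t_a + rows$t_b) / 2,
        function(m) tryCatch(suppressWarnings(cs_ratio(lab_s, ser_s, m)),
                             error = function(e) NA_real_),
        numeric(1))
    } else {
      rows$cs_ratio <- NA_real_
    }
    out[[s]] <- rows
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res
}
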