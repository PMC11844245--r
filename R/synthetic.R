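# Synthetic soil-microcosm community generator with planted ground truth.
# Taxa follow piecewise-exponential lag -> growth -> stationary -> death
# trajectories, so ln(N) is exactly piecewise linear in time and the
# window-regression detector is correctly specified on noiseless truth.

SUBSTRATES <- c("amino_acids", "palmitic_acid", "cellulose", "lignin", "xylose")

#' Sampling design of a litter-amendment microcosm time course
#'
#' Defaults reproduce the study design this package emulates: destructive
#' sampling every 12 h for days 0--7, daily for days 8--13, every 2 d for
#' days 15--27, plus day 30; three replicate microcosms per soil; an
#' internal spike-in standard targeted at ~5% of reads.
#'
#' @param days ordered sampling days (strictly increasing, >= 0).
#' @param replicates replicate microcosms per condition.
#' @param depth_mean,depth_sd mean and SD of per-sample sequencing depth;
#'   depths are drawn lognormal with these moments.
#' @param depth_min depths are clamped to at least this value (default twice
#'   the standard rarefaction depth so rarefaction never drops a sample).
#' @param istd_fraction target internal-standard read fraction, in (0, 1).
#' @return list of class `sampling_design`.
#' @export
default_design <- function(days = c(seq(0, 7, by = 0.5), 8:13, seq(15, 27, by = 2), 30),
                           replicates = 3L,
                           depth_mean = 5e4, depth_sd = 2e4,
                           depth_min = 2L * 8770L,
                           istd_fraction = 0.05) {
  if (is.unsorted(days, strictly = TRUE) || any(days < 0))
    stop("days must be strictly increasing and nonnegative")
  if (istd_fraction <= 0 || istd_fraction >= 1)
    stop("configuration error: istd_fraction must lie in (0, 1)")
  structure(list(days = days, replicates = as.integer(replicates),
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 depth_min = depth_min, istd_fraction = istd_fraction),
            class = "sampling_design")
}

validate_truth <- function(truth) {
  need <- c("asv_id", "strategy", "N0", "mu", "t_lag", "t_growth_end",
            "d", "t_death_start", "t_death_end", "yield_c", "rrn")
  miss <- setdiff(need, names(truth))
  if (length(miss)) stop("truth table missing columns: ", paste(miss, collapse = ", "))
  grow <- truth$mu > 0
  bad <- grow & !(truth$t_lag < truth$t_growth_end)
  if (any(bad)) stop("t_lag must precede t_growth_end for growing taxa")
  die <- truth$d > 0 & is.finite(truth$t_death_start)
  bad <- die & grow & truth$t_growth_end > truth$t_death_start
  if (any(bad)) stop("growth must end before death starts")
  invisible(truth)
}

#' Evaluate planted piecewise-exponential trajectories
#'
#' N(t) = N0 before the lag ends; grows exponentially at rate `mu` until
#' `t_growth_end`; holds a stationary plateau; then decays exponentially at
#' rate `d` over the death window. Continuous everywhere.
#'
#' @param truth data.frame of planted dynamics (see [archetype_truth()]).
#' @param days numeric vector of evaluation days.
#' @return matrix of true abundances, taxa x days.
#' @export
trajectory <- function(truth, days) {
  validate_truth(truth)
  stopifnot(all(days >= 0))
  one <- function(i) {
    N0 <- truth$N0[i]; mu <- truth$mu[i]; lag <- truth$t_lag[i]
    ge <- truth$t_growth_end[i]; d <- truth$d[i]
    ds <- truth$t_death_start[i]; de <- truth$t_death_end[i]
    plateau <- N0 * exp(mu * (ge - lag))
    n <- ifelse(days < lag, N0,
         ifelse(days <= ge, N0 * exp(mu * (days - lag)),
         ifelse(days < ds, plateau,
                plateau * exp(-d * (pmin(days, de) - ds)))))
    n
  }
  m <- t(vapply(seq_len(nrow(truth)), one, numeric(length(days))))
  dimnames(m) <- list(truth$asv_id, NULL)
  m
}

#' Closed-form planted abundance changes
#'
#' Gains and losses implied by the planted dynamics: `delta_Ng` is
#' N(t_growth_end) - N(t_lag), `delta_Nd` the plateau loss over the death
#' window. These are the ground truth the detector should recover.
#'
#' @inheritParams trajectory
#' @return `truth` with `delta_Ng` and `delta_Nd` columns appended.
#' @export
planted_deltas <- function(truth) {
  validate_truth(truth)
  plateau <- truth$N0 * exp(truth$mu * (truth$t_growth_end - truth$t_lag))
  truth$delta_Ng <- plateau - truth$N0
  dn <- ifelse(truth$d > 0 & is.finite(truth$t_death_start),
               plateau * (1 - exp(-truth$d * (truth$t_death_end - truth$t_death_start))),
               0)
  truth$delta_Nd <- dn
  truth
}

# growth-phase-only abundance at time t (plateau held after growth ends);
# used for CO2 coupling so death does not consume CO2.
growth_phase_n <- function(truth, t) {
  tc <- pmin(pmax(t, truth$t_lag), truth$t_growth_end)
  truth$N0 * exp(truth$mu * (tc - truth$t_lag))
}

#' Draw multinomial sequencing counts from planted trajectories
#'
#' For every replicate x day sample, a sequencing depth is drawn lognormal
#' and counts are multinomial with probabilities proportional to true
#' abundance times rrn copy number, plus one internal-standard category
#' whose true mass is constant across samples and chosen so that its
#' expected read share over the time course equals `design$istd_fraction`.
#'
#' @inheritParams trajectory
#' @param design a [default_design()] object.
#' @param seed integer seed; output is deterministic given the seed.
#' @param soil soil label written into the metadata.
#' @param isotope isotope label written into the metadata.
#' @return list with `counts` (taxa + "ISTD" row, samples in columns),
#'   `metadata` (sample, soil, day, replicate, isotope) and `istd_mass`.
#' @export
sample_counts <- function(truth, design, seed, soil = "soil1", isotope = "13C") {
  validate_truth(truth)
  if (nrow(truth) < 1) stop("need at least one taxon")
  if (inherits(design, "sampling_design") == FALSE)
    stop("design must come from default_design()")
  set.seed(seed)
  days <- design$days
  traj <- trajectory(truth, days)                      # taxa x days
  f <- design$istd_fraction
  istd_mass <- f / (1 - f) * mean(colSums(traj))
  nrep <- design$replicates
  nsamp <- length(days) * nrep
  counts <- matrix(0L, nrow(truth) + 1L, nsamp)
  meta <- data.frame(sample = character(nsamp), soil = soil,
                     day = 0, replicate = 0L, isotope = isotope)
  sdlog <- sqrt(log(1 + (design$depth_sd / design$depth_mean)^2))
  meanlog <- log(design$depth_mean) - sdlog^2 / 2
  k <- 0L
  for (r in seq_len(nrep)) {
    for (j in seq_along(days)) {
      k <- k + 1L
      depth <- max(design$depth_min, round(rlnorm(1, meanlog, sdlog)))
      prob <- c(traj[, j] * truth$rrn, istd_mass)
      counts[, k] <- rmultinom(1, depth, prob)[, 1]
      meta$sample[k] <- sprintf("%s_d%05.1f_r%d", soil, days[j], r)
      meta$day[k] <- days[j]
      meta$replicate[k] <- r
    }
  }
  rownames(counts) <- c(truth$asv_id, "ISTD")
  colnames(counts) <- meta$sample
  list(counts = counts, metadata = meta, istd_mass = istd_mass)
}

#' Simulate headspace CO2 accumulation coupled to planted growth
#'
#' CO2 mass accumulated per flushing interval equals a baseline (soil
#' organic matter respiration) plus `yield_c` times the growth-phase
#' abundance gain of each taxon, with multiplicative lognormal measurement
#' noise (mean 1). The 13C component carries the share produced by
#' litter-assigned taxa; baseline respiration is unlabeled. Optionally
#' blanks one flushing day to exercise the neighbor-mean imputation rule.
#'
#' @inheritParams sample_counts
#' @param baseline_rate baseline CO2 production (mass per day), >= 0.
#' @param flush_days days on which headspace was flushed and measured;
#'   default daily through day 15 then every second day through day 29.
#' @param noise_cv coefficient of variation of measurement noise.
#' @param blank_day flushing day whose measurements are set missing
#'   (default 15, mirroring the instrument failure scenario); NULL for none.
#' @return data.frame: microcosm, soil, replicate, day, co2_12, co2_13.
#' @export
simulate_co2 <- function(truth, design, baseline_rate = 1, seed = 1,
                         soil = "soil1",
                         flush_days = c(1:15, seq(17, 29, by = 2)),
                         noise_cv = 0.05, blank_day = 15) {
  validate_truth(truth)
  if (baseline_rate < 0) stop("baseline_rate must be >= 0")
  set.seed(seed)
  litter <- if ("litter" %in% names(truth)) truth$litter else rep(TRUE, nrow(truth))
  bounds <- c(0, flush_days)
  sdlog <- sqrt(log(1 + noise_cv^2))
  out <- list()
  for (r in seq_len(design$replicates)) {
    for (j in seq_along(flush_days)) {
      a <- bounds[j]; b <- bounds[j + 1]
      dng <- growth_phase_n(truth, b) - growth_phase_n(truth, a)
      grow13 <- sum(truth$yield_c * dng * litter)
      grow12 <- sum(truth$yield_c * dng * !litter)
      noise <- rlnorm(2, -sdlog^2 / 2, sdlog)
      out[[length(out) + 1L]] <- data.frame(
        microcosm = sprintf("%s_r%d", soil, r), soil = soil, replicate = r,
        day = flush_days[j],
        co2_12 = (baseline_rate * (b - a) + grow12) * noise[1],
        co2_13 = grow13 * noise[2])
    }
  }
  co2 <- do.call(rbind, out)
  if (!is.null(blank_day)) {
    hit <- co2$day == blank_day
    co2$co2_12[hit] <- NA_real_
    co2$co2_13[hit] <- NA_real_
  }
  co2
}

# parameter ranges for the three planted life-history archetypes.
# Ruderals: short lag, fast growth, short duration, frequent boom-bust
# death. Competitors: larger gains (high N0 and long growth), broad
# substrate use. Scarcity-adapted: long slow growth, smallest gains and
# losses, narrow substrate use. Ranges keep standardized archetype
# centers >= 3 SD apart so clustering recovery is well posed.
archetype_params <- function(strategy, n) {
  switch(strategy,
    R = data.frame(
      t_lag = runif(n, 0.5, 1.5), mu = runif(n, 1.2, 1.8),
      dur = runif(n, 1.5, 2.5), N0 = exp(runif(n, log(0.2), log(0.8))),
      d = runif(n, 0.3, 0.6), death_gap = runif(n, 1, 3),
      death_dur = runif(n, 4, 8), p_death = 0.9,
      ns_lo = 1L, ns_hi = 3L, rrn_lo = 3L, rrn_hi = 6L),
    C = data.frame(
      t_lag = runif(n, 3, 4.5), mu = runif(n, 0.45, 0.7),
      dur = runif(n, 4, 6), N0 = runif(n, 2, 5),
      d = runif(n, 0.1, 0.25), death_gap = runif(n, 2, 4),
      death_dur = runif(n, 6, 10), p_death = 0.5,
      ns_lo = 4L, ns_hi = 5L, rrn_lo = 2L, rrn_hi = 4L),
    S = data.frame(
      t_lag = runif(n, 4, 6), mu = runif(n, 0.08, 0.14),
      dur = runif(n, 9, 13), N0 = runif(n, 0.3, 0.6),
      d = runif(n, 0.04, 0.08), death_gap = runif(n, 1, 3),
      death_dur = runif(n, 4, 6), p_death = 0.2,
      ns_lo = 0L, ns_hi = 1L, rrn_lo = 1L, rrn_hi = 2L),
    stop("unknown strategy: ", strategy))
}

#' Planted truth table for the R/C/S archetype fixture
#'
#' Draws `n_per` taxa from each of the ruderal (R), competitive (C) and
#' scarcity-adapted (S) archetypes plus `n_null` flat taxa with no
#' dynamics (ground-truth negatives for FDR evaluation). Substrate
#' incorporation flags, rrn copy numbers, CO2 yields and litter-use flags
#' are drawn per taxon.
#'
#' @param n_per taxa per growth strategy.
#' @param n_null flat null taxa.
#' @param soil soil label used in ASV ids.
#' @param seed integer seed.
#' @param abundance_scale multiplies all initial abundances (models soils
#'   with more or less total DNA).
#' @return data.frame, one row per taxon, with closed-form `delta_Ng`
#'   and `delta_Nd` appended.
#' @export
archetype_truth <- function(n_per = 30L, n_null = 30L, soil = "meadow",
                            seed = 1, abundance_scale = 1) {
  set.seed(seed)
  rows <- list()
  for (strat in c("R", "C", "S")) {
    p <- archetype_params(strat, n_per)
    die <- runif(n_per) < p$p_death
    ns <- sample(seq(p$ns_lo[1], p$ns_hi[1]), n_per, replace = TRUE)
    flags <- t(vapply(ns, function(k) {
      f <- logical(5); f[sample.int(5, k)] <- TRUE; f
    }, logical(5)))
    colnames(flags) <- SUBSTRATES
    rows[[strat]] <- data.frame(
      asv_id = sprintf("%s_%s%03d", soil, strat, seq_len(n_per)),
      strategy = strat,
      N0 = p$N0 * abundance_scale,
      mu = p$mu,
      t_lag = p$t_lag,
      t_growth_end = p$t_lag + p$dur,
      d = ifelse(die, p$d, 0),
      t_death_start = ifelse(die, p$t_lag + p$dur + p$death_gap, Inf),
      t_death_end = ifelse(die, p$t_lag + p$dur + p$death_gap + p$death_dur, Inf),
      yield_c = runif(n_per, 0.5, 1.5),
      rrn = sample(seq(p$rrn_lo[1], p$rrn_hi[1]), n_per, replace = TRUE),
      litter = runif(n_per) < 0.8,
      n_substrates = ns, flags)
  }
  if (n_null > 0) {
    zf <- matrix(FALSE, n_null, 5, dimnames = list(NULL, SUBSTRATES))
    rows$null <- data.frame(
      asv_id = sprintf("%s_null%03d", soil, seq_len(n_null)),
      strategy = "null",
      N0 = exp(runif(n_null, log(0.1), log(1))) * abundance_scale,
      mu = 0, t_lag = 0, t_growth_end = 0,
      d = 0, t_death_start = Inf, t_death_end = Inf,
      yield_c = 0, rrn = sample(1:4, n_null, replace = TRUE),
      litter = FALSE, n_substrates = 0L, zf)
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  planted_deltas(truth)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

mutate_dna <- function(seq, n_sub) {
  s <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(s), n_sub)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  paste(s, collapse = "")
}

#' Synthetic amplicon sequences and substrate profiles for a truth table
#'
#' Every taxon gets a random V4-length ASV sequence. Growing taxa that
#' incorporate at least one substrate get a matching OTU sequence from the
#' (synthetic) stable-isotope-probing reference, mutated at `n_sub`
#' positions so identity stays above the matching threshold; the OTU's
#' profile equals the taxon's planted flags. Other taxa get no near
#' neighbor in the OTU set.
#'
#' @inheritParams trajectory
#' @param seed integer seed.
#' @param seq_len sequence length (bp).
#' @param n_sub substitutions between an ASV and its matching OTU.
#' @return list: `asv_seqs`, `otu_seqs` (named character vectors),
#'   `profiles` (data.frame of OTU substrate flags).
#' @export
synth_sequences <- function(truth, seed = 1, seq_len = 250L, n_sub = 2L) {
  set.seed(seed)
  asv_seqs <- random_dna(nrow(truth), seq_len)
  names(asv_seqs) <- truth$asv_id
  has_profile <- truth$mu > 0 & truth$n_substrates > 0
  otu_ids <- paste0("OTU_", truth$asv_id[has_profile])
  otu_seqs <- vapply(asv_seqs[has_profile], mutate_dna, character(1), n_sub = n_sub)
  names(otu_seqs) <- otu_ids
  profiles <- data.frame(otu_id = otu_ids,
                         truth[has_profile, SUBSTRATES, drop = FALSE],
                         row.names = NULL)
  list(asv_seqs = asv_seqs, otu_seqs = otu_seqs, profiles = profiles)
}

#' Simulate a full two-soil microcosm experiment
#'
#' Convenience wrapper tying together [archetype_truth()],
#' [sample_counts()], [simulate_co2()] and [synth_sequences()] for each
#' soil, with per-soil seeds derived from one master seed.
#'
#' @param design a [default_design()].
#' @param n_per_strategy,n_null taxa per strategy / null taxa, per soil.
#' @param soils soil labels.
#' @param seed master integer seed.
#' @param baseline_rate baseline CO2 production per day.
#' @param abundance_scale named per-soil abundance multipliers.
#' @return list with combined `counts`, `metadata`, `truth`, `co2`, `rrn`
#'   table, `profiles`, `asv_seqs`, `otu_seqs`, and per-soil `istd_mass`.
#' @export
simulate_community <- function(design = default_design(), n_per_strategy = 30L,
                               n_null = 30L,
                               soils = c("agricultural", "meadow"),
                               seed = 1, baseline_rate = 1,
                               abundance_scale = c(agricultural = 1, meadow = 1.5)) {
  truths <- counts <- metas <- co2s <- list()
  istd_mass <- numeric(0)
  for (i in seq_along(soils)) {
    s <- soils[i]
    sc <- if (s %in% names(abundance_scale)) abundance_scale[[s]] else 1
    tr <- archetype_truth(n_per_strategy, n_null, soil = s,
                          seed = derive_seed(seed, i), abundance_scale = sc)
    cs <- sample_counts(tr, design, seed = derive_seed(seed, 100 + i), soil = s)
    co2s[[s]] <- simulate_co2(tr, design, baseline_rate,
                              seed = derive_seed(seed, 200 + i), soil = s)
    truths[[s]] <- tr
    counts[[s]] <- cs$counts
    metas[[s]] <- cs$metadata
    istd_mass[s] <- cs$istd_mass
  }
  truth <- do.call(rbind, c(truths, make.row.names = FALSE))
  truth$soil <- rep(soils, vapply(truths, nrow, 0L))
  # block-diagonal count matrix over soils sharing one ISTD row
  all_asv <- truth$asv_id
  all_samp <- unlist(lapply(counts, colnames), use.names = FALSE)
  big <- matrix(0, length(all_asv) + 1L, length(all_samp),
                dimnames = list(c(all_asv, "ISTD"), all_samp))
  for (s in soils) {
    m <- counts[[s]]
    big[rownames(m), colnames(m)] <- m
  }
  seqs <- synth_sequences(truth, seed = derive_seed(seed, 300))
  list(counts = big,
       metadata = do.call(rbind, c(metas, make.row.names = FALSE)),
       truth = truth,
       co2 = do.call(rbind, c(co2s, make.row.names = FALSE)),
       rrn = data.frame(asv_id = truth$asv_id, rrn = truth$rrn),
       profiles = seqs$profiles, asv_seqs = seqs$asv_seqs,
       otu_seqs = seqs$otu_seqs, istd_mass = istd_mass, seed = seed)
}

#' Write a simulated experiment to plain-text files
#'
#' @param sim result of [simulate_community()].
#' @param outdir output directory (created if absent).
#' @return named character vector of paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cm <- paste("seed:", sim$seed)
  p <- c(counts = file.path(outdir, "counts.tsv"),
         metadata = file.path(outdir, "metadata.tsv"),
         truth = file.path(outdir, "truth.tsv"),
         co2 = file.path(outdir, "co2.tsv"),
         rrn = file.path(outdir, "rrn.tsv"),
         profiles = file.path(outdir, "profiles.tsv"),
         asv_fasta = file.path(outdir, "asvs.fasta"),
         otu_fasta = file.path(outdir, "otus.fasta"))
  write_counts(sim$counts, p["counts"], cm)
  write_tsv(sim$metadata, p["metadata"], cm)
  write_tsv(sim$truth, p["truth"], cm)
  write_tsv(sim$co2, p["co2"], cm)
  write_tsv(sim$rrn, p["rrn"], cm)
  write_tsv(sim$profiles, p["profiles"], cm)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$asv_seqs), p["asv_fasta"])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$otu_seqs), p["otu_fasta"])
  invisible(p)
}
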