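make_seq <- function(seed, len = 200) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_at <- function(seq, pos) {
  s <- strsplit(seq, "")[[1]]
  for (p in pos) s[p] <- c(A = "C", C = "G", G = "T", T = "A")[s[p]]
  paste(s, collapse = "")
}

test_that("profile matching enforces the 97% identity boundary", {
  asv <- make_seq(1)
  # substitutions scattered through the interior so the optimal global
  # alignment stays gapless and identity is exactly (200 - k)/200
  otus <- c(OTU_hi = mutate_at(asv, c(40, 80, 120, 160)),        # 98.0%
            OTU_lo = mutate_at(asv, seq(25, 175, by = 25)))      # 96.5%
  prof <- data.frame(otu_id = c("OTU_hi", "OTU_lo"),
                     amino_acids = c(TRUE, TRUE), palmitic_acid = FALSE,
                     cellulose = c(FALSE, TRUE), lignin = FALSE,
                     xylose = FALSE)
  out <- match_profiles(c(asv1 = asv), otus, prof)
  expect_equal(out$matched_otu, "OTU_hi")     # 96.5% discarded, 98.0% kept
  expect_equal(out$identity, 98.0)
  expect_true(out$amino_acids)
  expect_false(out$cellulose)
  expect_equal(out$n_substrates, 1L)
  # below threshold on both: unmatched, all-false profile
  far <- c(OTU_far = mutate_at(asv, seq(15, 195, by = 20)))  # 10 subs: 95%
  out2 <- match_profiles(c(asv1 = asv), far,
                         data.frame(otu_id = "OTU_far", amino_acids = TRUE,
                                    palmitic_acid = FALSE, cellulose = FALSE,
                                    lignin = FALSE, xylose = FALSE))
  expect_true(is.na(out2$matched_otu))
  expect_equal(out2$n_substrates, 0L)
})

test_that("exactly tied matches take the union of substrate profiles", {
  asv <- make_seq(2)
  otus <- c(OTU_a = mutate_at(asv, c(3, 50)), OTU_b = mutate_at(asv, c(90, 150)))
  prof <- data.frame(otu_id = c("OTU_a", "OTU_b"),
                     amino_acids = FALSE, palmitic_acid = FALSE,
                     cellulose = c(TRUE, FALSE), lignin = FALSE,
                     xylose = c(FALSE, TRUE))
  out <- match_profiles(c(asv1 = asv), otus, prof)
  expect_true(out$cellulose && out$xylose)
  expect_equal(out$n_substrates, 2L)
  # symmetric in tie order and idempotent
  out2 <- match_profiles(c(asv1 = asv), rev(otus), prof)
  expect_equal(out2$n_substrates, 2L)
  expect_equal(out2[SUBSTRATES_COLS <- c("cellulose", "xylose")],
               out[SUBSTRATES_COLS])
  expect_error(match_profiles(character(0), otus, prof), "empty")
})

lh_fixture <- function(n = 12, seed = 3) {
  set.seed(seed)
  data.frame(asv_id = sprintf("a%02d", 1:n), soil = "m",
             mu = runif(n, 0.2, 1), generation_time = runif(n, 0.5, 4),
             lag = runif(n, 0, 5), end_day = runif(n, 4, 12),
             duration = runif(n, 2, 8), N_start = runif(n, 0.1, 2),
             N_end = 1, delta_Ng = runif(n, 0.5, 30), p_slope = 0.001,
             r2 = 0.9, n_points = 6L, n_replicates = 2L)
}

test_that("feature transform applies documented offsets and standardizes", {
  ga <- lh_fixture()
  ga$lag[1] <- 0
  prof <- data.frame(asv_id = ga$asv_id[1:3], n_substrates = c(0L, 2L, 5L))
  bf <- build_features(ga, prof)
  f <- bf$features
  expect_equal(dim(f), c(12, 7))
  expect_equal(unname(colMeans(f)), rep(0, 7), tolerance = 1e-9)
  expect_equal(unname(apply(f, 2, sd)), rep(1, 7), tolerance = 1e-9)
  # zero-capable columns use ln(x + 1): n_substrates 0 -> 0 before scaling
  expect_equal(bf$raw$n_substrates[1], 0L)
  expect_equal(bf$raw$n_substrates[4], 0L)     # absent from profiles
  # strictly positive columns reject nonpositive input
  bad <- ga; bad$delta_Ng[2] <- 0
  expect_error(build_features(bad, prof), "nonpositive")
  # constant column is flagged
  const <- ga; const$duration <- 3
  expect_error(build_features(const, prof), "zero-variance")
})

test_that("clustering recovers separable planted archetypes", {
  truth <- archetype_truth(25, 0, seed = 9)
  ga <- data.frame(asv_id = truth$asv_id, soil = "m",
                   mu = truth$mu, generation_time = log(2) / truth$mu,
                   lag = truth$t_lag, end_day = truth$t_growth_end,
                   duration = truth$t_growth_end - truth$t_lag,
                   N_start = truth$N0, N_end = 1, delta_Ng = truth$delta_Ng,
                   p_slope = 0, r2 = 1, n_points = 6L, n_replicates = 3L)
  prof <- data.frame(asv_id = truth$asv_id, n_substrates = truth$n_substrates)
  bf <- build_features(ga, prof)
  cl <- cluster_lifehistory(bf$features, k = 3, seed = 5)
  lab <- label_clusters(bf$features, cl$cluster)
  expect_gte(mean(lab$labels == truth$strategy), 0.95)
  # permuting feature column order leaves the partition unchanged
  cl2 <- cluster_lifehistory(bf$features[, 7:1], k = 3, seed = 5)
  expect_equal(unname(cl2$cluster), unname(cl$cluster))
  # k = 1: a single cluster whose WCSS is the total sum of squares
  cl1 <- cluster_lifehistory(bf$features, k = 1, seed = 5)
  expect_equal(cl1$kmeans$tot.withinss, sum(scale(bf$features, scale = FALSE)^2))
  expect_error(cluster_lifehistory(bf$features[1:2, ], k = 3), "k exceeds")
})

test_that("cluster labels follow the generation-time / delta_Ng rule", {
  set.seed(8)
  f <- matrix(rnorm(30 * 7, 0, 0.1), 30, 7,
              dimnames = list(NULL, c("generation_time", "lag",
                                      "end_of_growth_day", "duration",
                                      "N_start", "delta_Ng", "n_substrates")))
  cl <- rep(1:3, each = 10)
  f[cl == 2, "generation_time"] <- f[cl == 2, "generation_time"] - 3  # fastest
  f[cl == 1, "delta_Ng"] <- f[cl == 1, "delta_Ng"] + 5                # big gains
  f[cl == 3, "delta_Ng"] <- f[cl == 3, "delta_Ng"] - 1
  lab <- label_clusters(f, cl)
  expect_equal(unname(lab$map[c("1", "2", "3")]), c("C", "R", "S"))
  # swapping cluster ids relabels identically per member
  cl_swapped <- c(3L, 1L, 2L)[cl]
  lab2 <- label_clusters(f, cl_swapped)
  expect_equal(unname(lab2$labels), unname(lab$labels))
})

test_that("cluster contrasts use Welch tests with Holm adjustment", {
  set.seed(4)
  value <- c(rnorm(12, 0), rnorm(12, 2), rnorm(12, 0.3))
  group <- rep(c("R", "C", "S"), each = 12)
  out <- compare_clusters(value, group)
  expect_s3_class(out$omnibus, "htest")
  expect_equal(nrow(out$contrasts), 3)
  expect_true(all(out$contrasts$p_holm >= out$contrasts$p_raw))
  # Holm by hand on a 2-test family: (0.01, 0.04) -> (0.02, 0.04)
  expect_equal(p.adjust(c(0.01, 0.04), "holm"), c(0.02, 0.04))
  # identical groups: p near 1
  same <- compare_clusters(rep(c(1, 2, 3, 4), 2), rep(c("a", "b"), each = 4))
  expect_gt(same$contrasts$p_raw, 0.95)
  expect_warning(
    compare_clusters(c(1, 2, 3, 2, 4, 6, 9), rep(c("a", "b", "c"), c(3, 3, 1))),
    "skipped")
})

test_that("substrate-count independence test runs on planted differences", {
  truth <- archetype_truth(25, 0, seed = 10)
  out <- compare_substrate_counts(truth$strategy, truth$n_substrates)
  expect_lt(out$omnibus$p.value, 0.05)
  expect_true(all(out$contrasts$p_holm >= out$contrasts$p_raw))
})
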