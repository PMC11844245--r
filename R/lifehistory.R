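# Life-history strategy assignment: 7-feature table, per-soil k-means
# (k = 3), rule-based mapping of clusters to R/C/S labels, and substrate
# incorporation profiles attached by pairwise sequence identity.

FEATURES <- c("generation_time", "lag", "end_of_growth_day", "duration",
              "N_start", "delta_Ng", "n_substrates")
# columns that can legitimately be zero get a +1 offset before ln
LN_OFFSET1 <- c("lag", "end_of_growth_day", "n_substrates")

#' Match ASVs to substrate-incorporation reference OTUs by identity
#'
#' Globally aligns each ASV sequence against every reference OTU
#' sequence, computes percent identity as matches over alignment columns,
#' and keeps only matches at or above `min_identity` (default 97).
#' Among qualifying OTUs the best match is the highest identity, with
#' longer alignment as tie-break (a deterministic, database-free
#' surrogate for e-value ranking); OTUs tied on both take the union of
#' their substrate flags. Unmatched ASVs get an all-false profile.
#'
#' @param asv_seqs named character vector or `DNAStringSet` of ASV
#'   sequences.
#' @param otu_seqs named character vector or `DNAStringSet` of reference
#'   OTU sequences.
#' @param otu_profiles data.frame: `otu_id` plus logical columns
#'   amino_acids, palmitic_acid, cellulose, lignin, xylose.
#' @param min_identity retention threshold in percent (default 97).
#' @return data.frame per ASV: asv_id, matched_otu (comma-separated if
#'   tied, NA if none), identity, the five flags, n_substrates.
#' @export
match_profiles <- function(asv_seqs, otu_seqs, otu_profiles, min_identity = 97) {
  if (!length(asv_seqs) || !length(otu_seqs))
    stop("data error: empty sequence set")
  asv <- Biostrings::DNAStringSet(asv_seqs)
  otu <- Biostrings::DNAStringSet(otu_seqs)
  stopifnot(all(otu_profiles$otu_id %in% names(otu)))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  rows <- lapply(seq_along(asv), function(i) {
    aln <- Biostrings::pairwiseAlignment(otu, asv[[i]], type = "global",
                                         substitutionMatrix = submat,
                                         gapOpening = 5, gapExtension = 2)
    ident <- Biostrings::pid(aln, type = "PID1")
    alen <- Biostrings::nchar(aln)
    ok <- ident >= min_identity
    prof <- stats::setNames(rep(FALSE, length(SUBSTRATES)), SUBSTRATES)
    if (!any(ok)) {
      return(data.frame(asv_id = names(asv)[i], matched_otu = NA_character_,
                        identity = NA_real_, t(prof),
                        n_substrates = 0L))
    }
    cand <- which(ok)
    best <- cand[order(-ident[cand], -alen[cand])]
    top <- best[ident[best] == ident[best[1]] & alen[best] == alen[best[1]]]
    ids <- names(otu)[top]
    pr <- otu_profiles[match(ids, otu_profiles$otu_id), SUBSTRATES, drop = FALSE]
    prof <- apply(as.matrix(pr), 2, any)
    data.frame(asv_id = names(asv)[i], matched_otu = paste(ids, collapse = ","),
               identity = ident[top[1]], t(prof),
               n_substrates = sum(prof))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the 7-feature life-history table for one soil
#'
#' Features per ASV: averaged generation time, lag time, end-of-growth
#' day, growth duration, starting normalized abundance, delta_Ng, and
#' number of substrates incorporated. Each is natural-log transformed --
#' ln(x) for strictly positive columns, ln(x + 1) for columns that can be
#' zero (lag, end-of-growth day, substrate count) -- then z-scaled within
#' the soil.
#'
#' @param growth_avg replicate-averaged growth estimates for one soil
#'   (from [average_replicates()]).
#' @param profiles per-ASV substrate profiles (from [match_profiles()]);
#'   ASVs absent from it get n_substrates = 0.
#' @return list: `raw` (data.frame of untransformed features keyed by
#'   asv_id/soil) and `features` (scaled matrix, ASVs in rows).
#' @export
build_features <- function(growth_avg, profiles = NULL) {
  if (length(unique(growth_avg$soil)) > 1)
    stop("build_features expects a single soil; cluster each soil separately")
  ns <- if (is.null(profiles)) rep(0L, nrow(growth_avg)) else {
    i <- match(growth_avg$asv_id, profiles$asv_id)
    ifelse(is.na(i), 0L, profiles$n_substrates[i])
  }
  raw <- data.frame(asv_id = growth_avg$asv_id, soil = growth_avg$soil,
                    generation_time = growth_avg$generation_time,
                    lag = growth_avg$lag,
                    end_of_growth_day = growth_avg$end_day,
                    duration = growth_avg$duration,
                    N_start = growth_avg$N_start,
                    delta_Ng = growth_avg$delta_Ng,
                    n_substrates = ns)
  m <- as.matrix(raw[FEATURES])
  strict <- setdiff(FEATURES, LN_OFFSET1)
  if (any(m[, strict] <= 0))
    stop("data error: nonpositive value in a strictly positive feature")
  if (any(m[, LN_OFFSET1] < 0))
    stop("data error: negative value in a nonnegative feature")
  m[, strict] <- log(m[, strict])
  m[, LN_OFFSET1] <- log(m[, LN_OFFSET1] + 1)
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    stop("data error: zero-variance feature column(s): ",
         paste(FEATURES[sds == 0], collapse = ", "))
  feat <- scale(m)
  rownames(feat) <- raw$asv_id
  list(raw = raw, features = feat)
}

#' k-means clustering of life-history features
#'
#' Squared-Euclidean k-means with multiple random restarts, keeping the
#' best partition by total within-cluster sum of squares. Also emits the
#' diagnostics used to justify the cluster number: the WCSS-vs-k curve
#' (k = 1..8) and the PCA cumulative-variance curve.
#'
#' @param features scaled feature matrix from [build_features()].
#' @param k number of clusters (default 3).
#' @param seed integer seed; deterministic given the seed.
#' @param n_restarts random restarts (default 25).
#' @return list: `cluster` (named integer vector), `kmeans` (the fit),
#'   `wcss_curve`, `pca_cumvar`.
#' @export
cluster_lifehistory <- function(features, k = 3L, seed = 1, n_restarts = 25L) {
  if (k > nrow(features))
    stop("configuration error: k exceeds the number of ASVs")
  set.seed(seed)
  km <- kmeans(features, centers = k, nstart = n_restarts, iter.max = 100)
  kmax <- min(8L, nrow(features) - 1L)
  wcss <- vapply(seq_len(kmax), function(kk)
    kmeans(features, centers = kk, nstart = 10, iter.max = 100)$tot.withinss,
    numeric(1))
  pca <- prcomp(features)
  cumvar <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  list(cluster = stats::setNames(km$cluster, rownames(features)),
       kmeans = km,
       wcss_curve = data.frame(k = seq_len(kmax), wcss = wcss),
       pca_cumvar = cumvar)
}

#' Map k = 3 clusters to CSR strategy labels
#'
#' A fixed rule encoding the post-hoc contrasts that characterize the
#' strategies: the ruderal (R) cluster has the smallest mean transformed
#' generation time (fastest growth); of the remaining two, the
#' competitive (C) cluster has the larger mean delta_Ng and the
#' scarcity-adapted (S) cluster the smaller. An exact tie falls back to
#' shorter mean lag for R (reported via message).
#'
#' @param features scaled feature matrix.
#' @param cluster integer cluster ids (length nrow(features)).
#' @return list: `labels` (named character vector per ASV), `map`
#'   (cluster id -> label), `means` (per-cluster feature means used).
#' @export
label_clusters <- function(features, cluster) {
  ids <- sort(unique(cluster))
  if (length(ids) != 3) stop("labeling requires exactly 3 clusters")
  means <- t(vapply(ids, function(cl)
    colMeans(features[cluster == cl, , drop = FALSE]), numeric(ncol(features))))
  rownames(means) <- ids
  gt <- means[, "generation_time"]
  if (anyDuplicated(gt)) {
    message("generation-time tie between clusters; breaking by lag")
    r_i <- which.min(rank(gt, ties.method = "first") + rank(means[, "lag"]) / 10)
  } else r_i <- which.min(gt)
  rest <- setdiff(seq_along(ids), r_i)
  c_i <- rest[which.max(means[rest, "delta_Ng"])]
  s_i <- setdiff(rest, c_i)
  map <- character(3)
  map[c(r_i, c_i, s_i)] <- c("R", "C", "S")
  names(map) <- as.character(ids)
  labels <- map[as.character(cluster)]
  names(labels) <- rownames(features)
  list(labels = labels, map = map, means = means)
}

#' Compare a growth parameter between clusters
#'
#' Welch ANOVA omnibus plus all pairwise Welch t-tests with Holm
#' step-down adjustment across the contrast family. Groups with fewer
#' than two observations are skipped with a warning.
#'
#' @param value numeric parameter values.
#' @param group group (cluster/strategy) membership.
#' @param log_transform apply ln before testing (for right-skewed
#'   parameters).
#' @return list: `omnibus` (htest) and `contrasts` (data.frame with raw
#'   and Holm-adjusted p-values).
#' @export
compare_clusters <- function(value, group, log_transform = FALSE) {
  if (log_transform) value <- log(value)
  group <- as.character(group)
  sizes <- table(group)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("group(s) with < 2 observations skipped: ",
            paste(small, collapse = ", "))
    keep <- !group %in% small
    value <- value[keep]; group <- group[keep]
  }
  if (length(unique(group)) < 2)
    stop("need at least 2 groups with >= 2 observations")
  omni <- oneway.test(value ~ factor(group), var.equal = FALSE)
  prs <- combn(sort(unique(group)), 2, simplify = FALSE)
  con <- do.call(rbind, lapply(prs, function(pr) {
    tt <- t.test(value[group == pr[1]], value[group == pr[2]], var.equal = FALSE)
    data.frame(group1 = pr[1], group2 = pr[2],
               estimate = diff(rev(tt$estimate)) * -1,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value)
  }))
  con$p_holm <- p.adjust(con$p_raw, method = "holm")
  list(omnibus = omni, contrasts = con)
}

#' Test independence of cluster membership and substrate count
#'
#' Fisher exact test on the cluster-by-substrate-count contingency table,
#' with Holm-adjusted pairwise cluster contrasts.
#'
#' @param strategy strategy/cluster labels per ASV.
#' @param n_substrates substrate counts per ASV.
#' @return list: `omnibus` p-value and `contrasts` data.frame.
#' @export
compare_substrate_counts <- function(strategy, n_substrates) {
  tab <- table(strategy, n_substrates)
  omni <- fisher.test(tab, simulate.p.value = nrow(tab) * ncol(tab) > 12,
                      B = 1e4)
  prs <- combn(sort(unique(as.character(strategy))), 2, simplify = FALSE)
  con <- do.call(rbind, lapply(prs, function(pr) {
    sub <- strategy %in% pr
    t2 <- table(factor(strategy[sub], levels = pr), n_substrates[sub])
    ft <- fisher.test(t2, simulate.p.value = ncol(t2) > 6, B = 1e4)
    data.frame(group1 = pr[1], group2 = pr[2], p_raw = ft$p.value)
  }))
  con$p_holm <- p.adjust(con$p_raw, method = "holm")
  list(omnibus = omni, contrasts = con)
}

#' Full life-history stage: features, clustering, labels
#'
#' @param growth_avg replicate-averaged growth estimates (may span
#'   multiple soils; each soil is clustered separately to avoid
#'   environment-driven bias).
#' @param profiles per-ASV substrate profiles or NULL.
#' @param k clusters per soil (default 3).
#' @param seed integer seed.
#' @param n_restarts k-means restarts.
#' @return data.frame: asv_id, soil, raw features, cluster, strategy;
#'   per-soil diagnostics in attribute `diagnostics`.
#' @export
lifehistory_table <- function(growth_avg, profiles = NULL, k = 3L, seed = 1,
                              n_restarts = 25L) {
  out <- list(); diag <- list()
  for (s in unique(growth_avg$soil)) {
    bf <- build_features(growth_avg[growth_avg$soil == s, , drop = FALSE],
                         profiles)
    cl <- cluster_lifehistory(bf$features, k, seed = seed,
                              n_restarts = n_restarts)
    lab <- if (k == 3) label_clusters(bf$features, cl$cluster)
           else list(labels = as.character(cl$cluster), map = NULL, means = NULL)
    tab <- bf$raw
    tab$cluster <- unname(cl$cluster)
    tab$strategy <- unname(lab$labels)
    out[[s]] <- tab
    diag[[s]] <- list(wcss_curve = cl$wcss_curve, pca_cumvar = cl$pca_cumvar,
                      label_map = lab$map, cluster_means = lab$means)
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(res, "diagnostics") <- diag
  res
}
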