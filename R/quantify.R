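# Quantification: raw ASV counts -> internal-standard-normalized,
# rrn-copy-number-corrected abundance time series.

#' Rarefy a count table to even depth
#'
#' Uniform subsampling without replacement of each sample's counts to a
#' fixed depth (via [vegan::rrarefy]). Samples whose total is below the
#' depth are dropped with a warning. The internal-standard row, if
#' present, is subsampled along with everything else.
#'
#' @param counts numeric matrix, ASVs in rows, samples in columns.
#' @param depth target counts per sample (default 8770).
#' @param seed integer seed; deterministic given the seed.
#' @return rarefied count matrix (possibly fewer columns).
#' @export
rarefy <- function(counts, depth = 8770L, seed = 1) {
  if (depth <= 0) stop("configuration error: depth must be positive")
  totals <- colSums(counts)
  keep <- totals >= depth
  if (any(!keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(colnames(counts)[!keep], collapse = ", "))
  counts <- counts[, keep, drop = FALSE]
  if (ncol(counts) == 0) return(counts)
  set.seed(seed)
  out <- withCallingHandlers(
    t(vegan::rrarefy(t(counts), depth)),
    warning = function(w) {
      # vegan flags tables whose smallest nonzero entry exceeds 1 as
      # "not observed counts"; integer fixtures trip this harmlessly
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(out) <- "double"
  dimnames(out) <- dimnames(counts)
  out
}

#' Normalize ASV counts to the internal standard
#'
#' Divides every ASV count by the internal-standard count of its sample,
#' turning compositional reads into abundance ratios comparable across
#' samples. Samples where the spike-in dropped out (zero counts) are
#' excluded with a warning, since the ratio is undefined there.
#'
#' @param counts numeric matrix including the internal-standard row.
#' @param istd_id row name of the internal standard (default "ISTD").
#' @return normalized abundance matrix without the internal-standard row.
#' @export
normalize_internal_standard <- function(counts, istd_id = "ISTD") {
  if (!istd_id %in% rownames(counts))
    stop("internal-standard row '", istd_id, "' not found")
  istd <- counts[istd_id, ]
  ok <- istd > 0
  if (any(!ok))
    warning(sum(!ok), " sample(s) with zero internal-standard counts excluded: ",
            paste(colnames(counts)[!ok], collapse = ", "))
  m <- counts[setdiff(rownames(counts), istd_id), ok, drop = FALSE]
  sweep(m, 2, istd[ok], "/")
}

#' Correct normalized abundances for 16S rrn copy number
#'
#' Divides each ASV's normalized abundance by its predicted per-genome
#' 16S gene copy number, converting read-based to organism-equivalent
#' abundance. ASVs absent from the table get `default_rrn` (reported).
#'
#' @param N normalized abundance matrix (ASVs x samples).
#' @param rrn data.frame with columns `asv_id`, `rrn`, or a named vector.
#' @param default_rrn copy number for ASVs missing from `rrn` (default 1,
#'   i.e. no correction).
#' @return corrected abundance matrix.
#' @export
correct_copy_number <- function(N, rrn, default_rrn = 1) {
  if (is.data.frame(rrn)) {
    v <- rrn$rrn
    names(v) <- rrn$asv_id
    rrn <- v
  }
  if (any(rrn < 1)) stop("data error: rrn copy numbers must be >= 1")
  cn <- rrn[rownames(N)]
  n_default <- sum(is.na(cn))
  if (n_default > 0)
    message(n_default, " ASV(s) missing from rrn table; default rrn = ",
            default_rrn, " applied")
  cn[is.na(cn)] <- default_rrn
  N / cn
}

#' Assemble per-ASV, per-replicate abundance time series
#'
#' Joins normalized abundances to sample metadata and produces one series
#' per (ASV, soil, replicate), ordered by day. ASVs detected (N > 0) at
#' fewer time points than the detector's minimum window length in every
#' replicate of a soil are flagged uninformative there: such series cannot
#' yield a growth or death estimate.
#'
#' @param N normalized (and corrected) abundance matrix.
#' @param metadata data.frame with columns sample, soil, day, replicate.
#' @param min_len detector's minimum window length (default 3).
#' @param drop_absent drop series with no nonzero observation (default TRUE).
#' @return long data.frame (asv_id, soil, replicate, day, N, informative),
#'   rows ordered by series then day, with attribute `uninformative`
#'   listing flagged (asv, soil) pairs.
#' @export
build_series <- function(N, metadata, min_len = 3L, drop_absent = TRUE) {
  need <- c("sample", "soil", "day", "replicate")
  stopifnot(all(need %in% names(metadata)))
  if (anyDuplicated(metadata$sample)) stop("data error: duplicate sample ids")
  common <- intersect(colnames(N), metadata$sample)
  if (length(common) < ncol(N))
    warning(ncol(N) - length(common), " sample(s) missing metadata dropped")
  N <- N[, common, drop = FALSE]
  md <- metadata[match(common, metadata$sample), ]
  if (anyDuplicated(paste(md$soil, md$replicate, md$day)))
    stop("data error: duplicate (soil, replicate, day) sample")
  long <- data.frame(
    asv_id = rep(rownames(N), times = ncol(N)),
    soil = rep(md$soil, each = nrow(N)),
    replicate = rep(md$replicate, each = nrow(N)),
    day = rep(md$day, each = nrow(N)),
    N = as.vector(N))
  if (drop_absent) {
    present <- tapply(long$N, paste(long$asv_id, long$soil, long$replicate,
                                    sep = "\r"), function(x) any(x > 0))
    key <- paste(long$asv_id, long$soil, long$replicate, sep = "\r")
    long <- long[present[key], ]
  }
  long <- long[order(long$asv_id, long$soil, long$replicate, long$day), ]
  rownames(long) <- NULL
  # informative = some replicate has >= min_len nonzero observations
  npos <- aggregate(list(npos = long$N > 0),
                    long[c("asv_id", "soil", "replicate")], sum)
  best <- aggregate(list(max_npos = npos$npos), npos[c("asv_id", "soil")], max)
  best$informative <- best$max_npos >= min_len
  long$informative <- best$informative[
    match(paste(long$asv_id, long$soil), paste(best$asv_id, best$soil))]
  attr(long, "uninformative") <- best[!best$informative, c("asv_id", "soil")]
  long
}

#' Full quantification stage: counts to normalized series
#'
#' Rarefaction (optional) -> internal-standard normalization -> rrn
#' correction -> series assembly, in that order.
#'
#' @inheritParams rarefy
#' @inheritParams build_series
#' @param metadata sample metadata (sample, soil, day, replicate).
#' @param rrn rrn copy-number table, or NULL to skip correction.
#' @param do_rarefy set FALSE to skip rarefaction (the ratio estimator
#'   does not require even depths).
#' @param istd_id internal-standard row id.
#' @return long series data.frame from [build_series()].
#' @export
quantify <- function(counts, metadata, rrn = NULL, depth = 8770L, seed = 1,
                     do_rarefy = TRUE, istd_id = "ISTD", min_len = 3L) {
  if (do_rarefy) counts <- rarefy(counts, depth, seed)
  N <- normalize_internal_standard(counts, istd_id)
  if (!is.null(rrn)) N <- correct_copy_number(N, rrn)
  build_series(N, metadata, min_len = min_len)
}
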