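#' Filter features by missing-value count
#'
#' Retains exactly the features with at most \code{maxMissing} missing
#' entries across all samples (the study rule: with 3 + 3 replicates, drop
#' proteins missing in more than two of the six). Order is preserved and the
#' operation is idempotent.
#'
#' @param x an [OmicsMatrix].
#' @param maxMissing maximum tolerated missing entries per feature; must be
#'   smaller than the number of samples.
#' @return The filtered [OmicsMatrix].
#' @export
filterMissing <- function(x, maxMissing = 2L) {
  stopifnot(is(x, "OmicsMatrix"))
  if (maxMissing >= ncol(x))
    stop("maxMissing must be smaller than the number of samples")
  keep <- rowSums(missingMask(x)) <= maxMissing
  if (!any(keep))
    warning("no features pass the missing-value filter")
  x[keep, ]
}

#' Log2 transform and per-feature Z-score normalization
#'
#' Applies \code{log2} elementwise to non-missing values, then standardizes
#' each feature row over its non-missing entries to mean 0 and sample SD
#' (n - 1 denominator) 1. Rows with zero SD are emitted as all-zero with a
#' warning. A column-wise Z-score is available via \code{margin}.
#'
#' @param x an [OmicsMatrix].
#' @param log2 apply the log2 transform (requires positive values).
#' @param zscore apply the Z-score standardization.
#' @param margin \code{"row"} (per feature, default) or \code{"column"}
#'   (per sample).
#' @return The normalized [OmicsMatrix].
#' @export
normalizeMatrix <- function(x, log2 = TRUE, zscore = TRUE,
                            margin = c("row", "column")) {
  stopifnot(is(x, "OmicsMatrix"))
  margin <- match.arg(margin)
  v <- omicsValues(x)
  if (log2) {
    bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-positive value under log2 at feature '%s', sample '%s'",
                   rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]))
    v <- base::log2(v)
  }
  if (zscore) {
    if (margin == "column") v <- t(v)
    mu <- rowMeans(v, na.rm = TRUE)
    sdev <- apply(v, 1L, stats::sd, na.rm = TRUE)
    zero <- !is.na(sdev) & sdev == 0
    if (any(zero)) {
      warning(sprintf("%d zero-SD %ss emitted as all-zero", sum(zero),
                      if (margin == "row") "feature row" else "sample column"))
      sdev[zero] <- 1
    }
    v <- (v - mu) / sdev
    if (margin == "column") v <- t(v)
  }
  assay(x, "exprs") <- v
  metadata(x)$normalized <- list(log2 = log2, zscore = zscore, margin = margin)
  x
}

# Vectorized per-feature two-group statistics on a values matrix with NAs.
# Returns a data.frame; features failing the >=2-per-group rule get NA stats
# and a reason. Means/variances use the same arithmetic as base mean/var.
.groupStats <- function(v, isA, s0) {
  a <- v[, isA, drop = FALSE]
  b <- v[, !isA, drop = FALSE]
  n1 <- rowSums(!is.na(a)); n2 <- rowSums(!is.na(b))
  m1 <- rowMeans(a, na.rm = TRUE); m2 <- rowMeans(b, na.rm = TRUE)
  ss1 <- rowSums((a - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((b - m2)^2, na.rm = TRUE)
  ok <- n1 >= 2 & n2 >= 2
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- m1 - m2
  t_raw <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff)))
  d_mod <- diff / (se + s0)
  if (s0 == 0) d_mod <- t_raw
  p <- 2 * stats::pt(abs(t_raw), df, lower.tail = FALSE)
  p[is.infinite(t_raw)] <- 0
  t_raw[!ok] <- NA; d_mod[!ok] <- NA; p[!ok] <- NA
  data.frame(feature_id = rownames(v), log2_fc = diff, t_raw = t_raw,
             d_mod = d_mod, p_raw = p, n_af = n1, n_sham = n2, ok = ok,
             reason = ifelse(ok, "", "fewer than 2 values per group"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-feature S0-moderated two-sample statistics
#'
#' For each feature: the pooled-variance two-sample Student t (\code{t_raw}),
#' the S0-moderated statistic \code{d_mod = (mean_AF - mean_sham) /
#' (SE_pooled + s0)} (the SAM-style fudge factor damping small fold changes),
#' and the two-sided p of \code{t_raw} at \code{n1 + n2 - 2} df. Features
#' with fewer than two non-missing values in either group are emitted with
#' \code{NA} statistics and a reason.
#'
#' @param x an [OmicsMatrix] (typically filtered and log2-transformed).
#' @param s0 moderation constant (>= 0); at \code{s0 = 0}, \code{d_mod}
#'   equals \code{t_raw} exactly.
#' @return data.frame with columns feature_id, log2_fc, t_raw, d_mod, p_raw,
#'   n_af, n_sham, ok, reason.
#' @export
moderatedT <- function(x, s0 = 0.1) {
  stopifnot(is(x, "OmicsMatrix"), s0 >= 0)
  g <- sampleGroups(x)
  lv <- unique(g)
  if (length(lv) != 2L) stop("exactly two groups are required")
  isA <- g == if ("AF" %in% lv) "AF" else lv[1]
  .groupStats(omicsValues(x), isA, s0)
}

# Distinct balanced relabelings: index sets of size n1 out of n (pseudo-AF).
.balancedSplits <- function(n, n1, nPermutations, seed) {
  total <- choose(n, n1)
  if (nPermutations >= total || total <= 1e4) {
    all <- utils::combn(n, n1)
    if (nPermutations >= total)
      return(list(splits = all, exhaustive = TRUE))
    if (!is.null(seed)) set.seed(seed)
    return(list(splits = all[, sample.int(ncol(all), nPermutations),
                             drop = FALSE],
                exhaustive = FALSE))
  }
  if (!is.null(seed)) set.seed(seed)
  seen <- new.env(hash = TRUE)
  out <- matrix(0L, n1, 0L)
  while (ncol(out) < nPermutations) {
    s <- sort(sample.int(n, n1))
    key <- paste(s, collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      out <- cbind(out, s)
    }
  }
  list(splits = out, exhaustive = FALSE)
}

#' Permutation-FDR volcano classification
#'
#' Computes the observed \code{|d_mod|} per feature, re-computes it under
#' balanced random group relabelings, and for candidate cutoffs c estimates
#' \deqn{\widehat{FDR}(c) = median_{perm} \#\{|d_{perm}| \ge c\} /
#'   \max(1, \#\{|d_{obs}| \ge c\}).}
#' The estimate is monotonized (running minimum over ascending c) and the
#' smallest cutoff with monotonized FDR at or below \code{fdrTarget} is
#' selected; features with \code{|d_obs| >= c} (ties significant) are flagged
#' with direction by the sign of the group difference. When the requested
#' number of relabelings meets or exceeds the number of distinct balanced
#' splits (20 for a 3-vs-3 design), all splits are enumerated exhaustively.
#'
#' @param x an [OmicsMatrix], filtered and normalized; both groups need at
#'   least two samples.
#' @param s0 moderation constant.
#' @param nPermutations requested number of relabelings (default 250).
#' @param fdrTarget target FDR (default 0.05).
#' @param seed optional seed for sampled (non-exhaustive) relabelings.
#' @return A [VolcanoResults-class] object.
#' @examples
#' sim <- simulateProteomics(SimStudyConfig(seed = 7, n_features = 200))
#' om <- normalizeMatrix(filterMissing(sim$matrix), zscore = FALSE)
#' permutationVolcano(om, seed = 7)
#' @export
permutationVolcano <- function(x, s0 = 0.1, nPermutations = 250L,
                               fdrTarget = 0.05, seed = NULL) {
  stopifnot(is(x, "OmicsMatrix"), nPermutations >= 1,
            fdrTarget > 0, fdrTarget < 1)
  g <- sampleGroups(x)
  lv <- unique(g)
  if (length(lv) != 2L) stop("exactly two groups are required")
  aLab <- if ("AF" %in% lv) "AF" else lv[1]
  isA <- g == aLab
  if (sum(isA) < 2 || sum(!isA) < 2)
    stop("both groups need at least 2 samples")
  v <- omicsValues(x)
  obs <- .groupStats(v, isA, s0)
  dObs <- abs(obs$d_mod)

  sp <- .balancedSplits(ncol(v), sum(isA), nPermutations, seed)
  nPerm <- ncol(sp$splits)
  if (sp$exhaustive && nPerm < nPermutations)
    message(sprintf("only %d distinct balanced splits; using exhaustive enumeration",
                    nPerm))
  cand <- sort(unique(dObs[is.finite(dObs)]))
  if (length(cand)) {
    obsCount <- vapply(cand, function(c) sum(dObs >= c, na.rm = TRUE), 0)
    falseCount <- matrix(0, nPerm, length(cand))
    for (p in seq_len(nPerm)) {
      isAp <- seq_len(ncol(v)) %in% sp$splits[, p]
      dp <- abs(.groupStats(v, isAp, s0)$d_mod)
      dp <- sort(dp[!is.na(dp)])
      falseCount[p, ] <- length(dp) -
        findInterval(cand, dp, left.open = TRUE)
    }
    fdrRaw <- apply(falseCount, 2L, stats::median) / pmax(1, obsCount)
    fdrMono <- cummin(fdrRaw)  # non-increasing in c
    sel <- which(fdrMono <= fdrTarget)
    if (length(sel)) {
      cutoff <- cand[sel[1]]
      fdrEst <- fdrMono[sel[1]]
    } else {
      cutoff <- Inf; fdrEst <- NA_real_
    }
  } else {
    cutoff <- Inf; fdrEst <- NA_real_
  }
  sig <- !is.na(dObs) & dObs >= cutoff
  direction <- ifelse(sig, ifelse(obs$log2_fc > 0, "up", "down"), "ns")
  res <- DataFrame(obs[, c("feature_id", "log2_fc", "t_raw", "d_mod",
                           "p_raw")],
                   significant = sig, direction = direction,
                   reason = obs$reason)
  new("VolcanoResults", results = res, cutoff = cutoff,
      fdrEst = as.numeric(fdrEst), nPermutations = as.integer(nPerm),
      exhaustive = sp$exhaustive,
      config = list(s0 = s0, n_permutations = nPermutations,
                    fdr_target = fdrTarget, group_a = aLab))
}

#' PCA sample scores and variance fractions
#'
#' Centered singular-value decomposition of the samples-by-features matrix.
#' Requires complete data (filter to fully observed features first; the study
#' performed PCA on 100 percent valid values).
#'
#' @param x an [OmicsMatrix] with no missing values.
#' @return list with \code{scores} (samples x components) and
#'   \code{fractions} (variance fractions, non-increasing, summing to 1);
#'   fractions are NA with a warning when the centered matrix is all-zero.
#' @export
pcaVariance <- function(x) {
  stopifnot(is(x, "OmicsMatrix"))
  v <- omicsValues(x)
  if (anyNA(v))
    stop("missing values present; filter to fully observed features first")
  m <- scale(t(v), center = TRUE, scale = FALSE)
  if (all(abs(m) < .Machine$double.eps * 100)) {
    warning("zero-variance data: variance fractions undefined")
    return(list(scores = m[, 0, drop = FALSE], fractions = NA_real_))
  }
  pc <- stats::prcomp(m, center = FALSE)
  fr <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, fractions = fr)
}

#' Pairwise-complete Pearson correlation between samples
#'
#' @param x an [OmicsMatrix].
#' @return symmetric sample-by-sample correlation matrix with unit diagonal;
#'   pairs sharing fewer than two observed features are NA and reported in
#'   attribute \code{"flagged_pairs"}.
#' @export
sampleCorrelation <- function(x) {
  stopifnot(is(x, "OmicsMatrix"))
  v <- omicsValues(x)
  obs <- !is.na(v)
  shared <- crossprod(obs)
  r <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs"))
  r[shared < 2] <- NA
  diag(r) <- 1
  bad <- which(shared < 2 & upper.tri(shared), arr.ind = TRUE)
  attr(r, "flagged_pairs") <- if (nrow(bad))
    data.frame(sample_a = colnames(v)[bad[, 1]],
               sample_b = colnames(v)[bad[, 2]]) else NULL
  r
}

#' K-means feature clusters and hierarchical display orders
#'
#' Euclidean K-means (multiple restarts under a fixed seed) labels each
#' feature; average-linkage hierarchical clustering on Euclidean distances
#' supplies the row and column display orders for a heatmap.
#'
#' @param x a normalized [OmicsMatrix] with no missing values.
#' @param k number of clusters (1 <= k <= number of features).
#' @param seed integer seed for the K-means restarts.
#' @param nstart K-means restarts.
#' @return list(labels, rowOrder, colOrder).
#' @export
clusterForHeatmap <- function(x, k, seed = 1L, nstart = 10L) {
  stopifnot(is(x, "OmicsMatrix"), k >= 1)
  v <- omicsValues(x)
  if (anyNA(v)) stop("missing values present; filter first")
  if (k > nrow(v)) stop("k exceeds the number of features")
  set.seed(seed)
  labels <- if (k == 1L) rep(1L, nrow(v)) else
    stats::kmeans(v, centers = k, nstart = nstart)$cluster
  names(labels) <- rownames(v)
  rowOrder <- if (nrow(v) > 2)
    stats::hclust(stats::dist(v), method = "average")$order else seq_len(nrow(v))
  colOrder <- if (ncol(v) > 2)
    stats::hclust(stats::dist(t(v)), method = "average")$order else seq_len(ncol(v))
  list(labels = labels, rowOrder = rowOrder, colOrder = colOrder)
}

#' Overlap between two identifier sets
#'
#' @param a,b character vectors of identifiers.
#' @return list(shared_pct = 100 * |intersection| / |union|, n_shared,
#'   n_a_only, n_b_only); the percentage is NA with a warning when both sets
#'   are empty.
#' @examples
#' listOverlap(c("P1", "P2", "P3"), c("P2", "P3", "P4", "P5"))$shared_pct  # 40
#' @export
listOverlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  nShared <- length(intersect(a, b))
  nUnion <- length(union(a, b))
  pct <- if (nUnion == 0) {
    warning("both sets empty: overlap undefined")
    NA_real_
  } else 100 * nShared / nUnion
  list(shared_pct = pct, n_shared = nShared,
       n_a_only = length(setdiff(a, b)), n_b_only = length(setdiff(b, a)))
}
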