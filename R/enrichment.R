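#' Generalized-log variance-stabilizing transform
#'
#' Samples are first affine-calibrated (per-sample scaling to a common
#' median and MAD), then transformed with
#' \deqn{glog(x) = \log_2\left(\frac{x + \sqrt{x^2 + c^2}}{2}\right),}
#' which equals \code{log2(x)} for \code{x >> c} and flattens the noise-
#' dominated low-intensity range, stabilizing the variance-mean relationship.
#'
#' @param x an [OmicsMatrix] with non-negative values.
#' @param c glog offset; \code{"auto"} (default) uses the 5th percentile of
#'   the calibrated positive values, \code{0} reduces to a plain log2.
#' @param calibrate apply the per-sample median/MAD affine calibration.
#' @return The transformed [OmicsMatrix].
#' @export
vstTransform <- function(x, c = "auto", calibrate = TRUE) {
  stopifnot(is(x, "OmicsMatrix"))
  v <- omicsValues(x)
  if (any(v < 0, na.rm = TRUE)) stop("values must be non-negative")
  if (any(colSums(!is.na(v)) == 0))
    stop("all-missing sample present")
  if (calibrate && ncol(v) > 1) {
    med <- apply(v, 2L, stats::median, na.rm = TRUE)
    madv <- apply(v, 2L, stats::mad, na.rm = TRUE)
    refMed <- stats::median(med); refMad <- stats::median(madv)
    sc <- ifelse(madv > 0, refMad / madv, 1)
    v <- sweep(sweep(v, 2L, med), 2L, sc, "*") + refMed
  }
  if (identical(c, "auto"))
    c <- stats::quantile(v[!is.na(v) & v > 0], 0.05, names = FALSE)
  g <- log2((v + sqrt(v^2 + c^2)) / 2)
  assay(x, "exprs") <- g
  metadata(x)$vst <- list(c = c, calibrated = calibrate)
  x
}

#' Map features onto a shared (human homolog) identifier space
#'
#' Features are renamed source -> target through the homolog map;
#' one-to-many source mappings duplicate the row onto each target, and
#' many-to-one collisions are collapsed elementwise by the chosen rule.
#' Unmapped features are dropped with a message.
#'
#' @param matrices a list of [OmicsMatrix] objects.
#' @param idmap data.frame with columns \code{source}, \code{target}.
#' @param collapse \code{"median"} (elementwise median over colliding rows)
#'   or \code{"max_abs"} (elementwise value of largest magnitude).
#' @return list of [OmicsMatrix] on the target id space.
#' @export
harmonizeIds <- function(matrices, idmap, collapse = c("median", "max_abs")) {
  collapse <- match.arg(collapse)
  stopifnot(is.list(matrices), all(c("source", "target") %in% colnames(idmap)))
  if (any(!nzchar(idmap$source)) || any(!nzchar(idmap$target)))
    stop("idmap contains empty ids")
  lapply(matrices, function(m) {
    stopifnot(is(m, "OmicsMatrix"))
    v <- omicsValues(m)
    hit <- idmap[idmap$source %in% rownames(v), , drop = FALSE]
    if (nrow(hit) == 0)
      stop(sprintf("no feature of dataset '%s' is covered by the id map",
                   datasetTag(m)))
    nDropped <- sum(!rownames(v) %in% idmap$source)
    if (nDropped > 0)
      message(sprintf("[%s] %d unmapped features dropped", datasetTag(m),
                      nDropped))
    ex <- v[hit$source, , drop = FALSE]
    tgt <- hit$target
    collapseFun <- if (collapse == "median")
      function(block) apply(block, 2L, stats::median, na.rm = TRUE)
    else
      function(block) apply(block, 2L, function(col) {
        if (all(is.na(col))) return(NA_real_)
        col[which.max(abs(col))]
      })
    ut <- unique(tgt)
    out <- t(vapply(ut, function(id) {
      block <- ex[tgt == id, , drop = FALSE]
      if (nrow(block) == 1L) as.numeric(block) else collapseFun(block)
    }, numeric(ncol(ex))))
    out[is.nan(out)] <- NA
    dimnames(out) <- list(ut, colnames(v))
    OmicsMatrix(out, sampleGroups(m), datasetTag(m))
  })
}

#' Flag outlier samples by PCA distance from the group centre
#'
#' Matrices are restricted to their shared feature ids, feature rows are
#' standardized, samples are projected onto the first two principal
#' components, and each sample's distance from its group's coordinate-wise
#' median is compared with \code{thresholdMad} times the MAD of all
#' within-group distances.
#'
#' @param matrices list of [OmicsMatrix] sharing a feature id space.
#' @param thresholdMad MAD multiplier (default 5).
#' @return character vector of flagged sample ids (possibly empty), with the
#'   per-sample distances in attribute \code{"distances"}. Errors if the
#'   removal would leave any group with fewer than two samples.
#' @export
detectOutlierSamples <- function(matrices, thresholdMad = 5) {
  if (is(matrices, "OmicsMatrix")) matrices <- list(matrices)
  shared <- Reduce(intersect, lapply(matrices, rownames))
  if (length(shared) < 3) stop("fewer than 3 shared features")
  vals <- do.call(cbind, lapply(matrices, function(m)
    omicsValues(m)[shared, , drop = FALSE]))
  groups <- unlist(lapply(matrices, sampleGroups))
  names(groups) <- colnames(vals)
  if (min(table(groups)) < 3) stop("at least 3 samples per group required")
  keep <- rowSums(is.na(vals)) == 0
  vals <- vals[keep, , drop = FALSE]
  sdv <- apply(vals, 1L, stats::sd)
  vals <- vals[sdv > 0, , drop = FALSE]
  z <- (vals - rowMeans(vals)) / apply(vals, 1L, stats::sd)
  pc <- stats::prcomp(t(z), center = TRUE)
  sc <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  dist <- numeric(nrow(sc)); names(dist) <- rownames(sc)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ctr <- apply(sc[idx, , drop = FALSE], 2L, stats::median)
    dist[idx] <- sqrt(rowSums(sweep(sc[idx, , drop = FALSE], 2L, ctr)^2))
  }
  if (!is.finite(thresholdMad))
    return(structure(character(), distances = dist))
  scale <- max(stats::mad(dist), .Machine$double.eps)
  flagged <- names(dist)[dist > thresholdMad * scale]
  remaining <- table(groups[setdiff(names(groups), flagged)])
  if (length(flagged) &&
      (length(remaining) < length(unique(groups)) || min(remaining) < 2))
    stop("outlier removal would leave a group with fewer than 2 samples; aborted")
  structure(flagged, distances = dist)
}

#' Per-gene pooled two-sample t statistics
#'
#' @param x an [OmicsMatrix].
#' @return data.frame(gene_id, t, status) where status is \code{"ok"},
#'   \code{"missing"} (fewer than 2 values in a group; t is NA) or
#'   \code{"degenerate"} (zero pooled SE with unequal means; t is a signed
#'   infinite sentinel which ranks to the extreme).
#' @export
geneTStats <- function(x) {
  stopifnot(is(x, "OmicsMatrix"))
  st <- moderatedT(x, s0 = 0)
  status <- ifelse(!st$ok, "missing",
                   ifelse(is.infinite(st$t_raw), "degenerate", "ok"))
  data.frame(gene_id = st$feature_id, t = st$t_raw, status = status,
             stringsAsFactors = FALSE)
}

#' Build per-dataset rank profiles with the cross-omics missing-value policy
#'
#' Within each dataset, genes with statistics are ranked ascending by t with
#' mid-ranks for ties (rank \code{n_d} = largest t = most AF-up). In each
#' proteomics dataset, a gene missing there but observed in at least one
#' proteomics dataset is \emph{ranked last}: the whole ranked-last block sits
#' at the bottom and shares its mid-rank \code{(L + 1) / 2}. A gene observed
#' only in the transcriptomics dataset is \emph{excluded} from every
#' proteomics ranking. Transcriptomics ranks cover exactly the genes with
#' transcript statistics.
#'
#' @param tstats named list (dataset tag -> named numeric vector of t
#'   statistics for the genes observed in that dataset; NA entries are
#'   treated as unobserved, infinite sentinels rank to the extremes).
#' @param proteomicsTags which list elements are proteomics datasets
#'   (default: every tag except \code{"RNA"}).
#' @return A \code{RankProfile}: list with \code{ranks} (per dataset, named
#'   rank vector over ranked + ranked-last genes), \code{status} (per
#'   dataset, \code{"ranked"} or \code{"ranked_last"}), \code{n} (ranked
#'   universe size per dataset), \code{datasets}, \code{proteomics}.
#' @export
rankDatasets <- function(tstats,
                         proteomicsTags = setdiff(names(tstats), "RNA")) {
  stopifnot(is.list(tstats), !is.null(names(tstats)))
  observed <- lapply(tstats, function(v) names(v)[!is.na(v)])
  protObserved <- unique(unlist(observed[proteomicsTags]))
  ranks <- list(); status <- list(); n <- integer()
  for (d in names(tstats)) {
    obsIds <- observed[[d]]
    lastIds <- if (d %in% proteomicsTags)
      setdiff(protObserved, obsIds) else character()
    L <- length(lastIds); m <- length(obsIds)
    nd <- L + m
    r <- numeric(nd); s <- character(nd)
    if (L) {
      r[seq_len(L)] <- (L + 1) / 2
      s[seq_len(L)] <- "ranked_last"
    }
    if (m) {
      r[L + seq_len(m)] <- L + rank(tstats[[d]][obsIds], ties.method = "average")
      s[L + seq_len(m)] <- "ranked"
    }
    names(r) <- names(s) <- c(lastIds, obsIds)
    ranks[[d]] <- r; status[[d]] <- s; n[d] <- nd
    if (m < 2 && d %in% proteomicsTags)
      warning(sprintf("dataset '%s' has fewer than 2 ranked genes", d))
  }
  structure(list(ranks = ranks, status = status, n = n,
                 datasets = names(tstats), proteomics = proteomicsTags),
            class = "RankProfile")
}

#' Normalized per-dataset rank score of a gene category
#'
#' \deqn{score_d = \frac{2}{n_d}\left(\bar R_d - \frac{n_d + 1}{2}\right)}
#' is bounded in (-1, 1); positive values mean the members sit toward the
#' AF-up end of the ranking. The score of the full universe is exactly 0.
#'
#' @param profile a \code{RankProfile} from [rankDatasets()].
#' @param members character vector of member gene ids.
#' @return named numeric vector of scores, one per dataset; NA when no
#'   member carries a rank in that dataset.
#' @export
categoryScores <- function(profile, members) {
  stopifnot(inherits(profile, "RankProfile"))
  vapply(profile$datasets, function(d) {
    r <- profile$ranks[[d]]
    mr <- r[names(r) %in% members]
    if (!length(mr)) return(NA_real_)
    nd <- profile$n[[d]]
    (2 / nd) * (mean(mr) - (nd + 1) / 2)
  }, numeric(1))
}

# Spearman correlation matrix of the rank columns over genes ranked in each
# pair of datasets; identity fallback for pairs with < 3 common genes.
.rankCorrelation <- function(profile) {
  D <- length(profile$datasets)
  C <- diag(1, D)
  dimnames(C) <- list(profile$datasets, profile$datasets)
  for (i in seq_len(D - 1)) for (j in (i + 1):D) {
    ri <- profile$ranks[[i]]; rj <- profile$ranks[[j]]
    common <- intersect(names(ri), names(rj))
    if (length(common) >= 3) {
      r <- stats::cor(ri[common], rj[common], method = "spearman")
      if (is.finite(r)) C[i, j] <- C[j, i] <- r
    }
  }
  C
}

#' Joint rank-enrichment MANOVA test for one gene category
#'
#' Each dataset's mean member rank is standardized with the
#' sampling-without-replacement (Wilcoxon) variance,
#' \deqn{z_d = \frac{\bar R_d - (n_d + 1) / 2}
#'   {\sqrt{(n_d - k_d)(n_d + 1) / (12 k_d)}},}
#' the cross-dataset dependence is estimated as the Spearman correlation of
#' the full rank columns, and \eqn{T^2 = z^\top \hat C^{-1} z} is referred to
#' a chi-square with one degree of freedom per dataset. With a single
#' dataset this reduces to the normal-approximation Wilcoxon rank-sum test
#' of members versus non-members.
#'
#' @param profile a \code{RankProfile}.
#' @param members character vector of member gene ids.
#' @param minPerSide membership floor: minimum members with valid ranks
#'   required in every dataset entering the test (default 2).
#' @param rankCor optional pre-computed Spearman correlation matrix of the
#'   rank columns (saves recomputation across many categories).
#' @return list(T2, p, z, k, skipped, reason); when the floor is not met,
#'   \code{skipped} is TRUE and the test statistics are NA.
#' @export
manovaEnrichmentTest <- function(profile, members, minPerSide = 2L,
                                 rankCor = NULL) {
  stopifnot(inherits(profile, "RankProfile"))
  D <- length(profile$datasets)
  k <- integer(D); z <- numeric(D)
  names(k) <- names(z) <- profile$datasets
  for (d in profile$datasets) {
    r <- profile$ranks[[d]]
    mr <- r[names(r) %in% members]
    k[d] <- length(mr)
    nd <- profile$n[[d]]
    if (k[d] == 0 || k[d] == nd) { z[d] <- 0; next }
    vr <- (nd - k[d]) * (nd + 1) / (12 * k[d])
    z[d] <- (mean(mr) - (nd + 1) / 2) / sqrt(vr)
  }
  if (any(k < minPerSide))
    return(list(T2 = NA_real_, p = NA_real_, z = z, k = k, skipped = TRUE,
                reason = sprintf("fewer than %d ranked members in dataset(s) %s",
                                 minPerSide,
                                 paste(names(k)[k < minPerSide], collapse = ","))))
  C <- if (is.null(rankCor)) .rankCorrelation(profile) else rankCor
  Ci <- tryCatch(solve(C), error = function(e) NULL)
  if (is.null(Ci)) {
    warning("singular rank correlation matrix; ridge-regularized")
    Ci <- solve(C + diag(1e-6, nrow(C)))
  }
  T2 <- as.numeric(z %*% Ci %*% z)
  list(T2 = T2, p = stats::pchisq(T2, df = D, lower.tail = FALSE),
       z = z, k = k, skipped = FALSE, reason = "")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up q-values: monotone, with \code{q >= p} everywhere. The
#' \code{"storey"} option rescales by a Storey pi0 estimate
#' (lambda = 0.5), an empirical-null flavoured variant.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param method \code{"BH"} (default) or \code{"storey"}.
#' @return numeric vector of q-values.
#' @export
qValues <- function(p, method = c("BH", "storey")) {
  method <- match.arg(method)
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, mean(p > 0.5, na.rm = TRUE) / 0.5)
    q <- pmin(1, q * pi0)
  }
  q
}

#' Significance call and confidence tier from q-values
#'
#' @param q numeric q-values.
#' @param fdrThreshold significance threshold (default 0.01, i.e. 1\% FDR).
#' @param highThreshold q below which a pathway is highly confident
#'   (default 0.001).
#' @return data.frame(q, significant, tier) with tier in
#'   \code{non_confident} / \code{confident} / \code{highly_confident}.
#' @export
classifyTiers <- function(q, fdrThreshold = 0.01, highThreshold = 0.001) {
  tier <- ifelse(is.na(q), NA_character_,
                 ifelse(q < highThreshold, "highly_confident",
                        ifelse(q < fdrThreshold, "confident", "non_confident")))
  data.frame(q = q, significant = !is.na(q) & q < fdrThreshold, tier = tier,
             stringsAsFactors = FALSE)
}

#' Integrated multi-dataset pathway enrichment analysis
#'
#' End-to-end driver: per-gene t statistics in every dataset, rank profiles
#' under the cross-omics missing-value policy, per-pathway rank scores and
#' the joint rank-enrichment MANOVA, BH q-values and confidence tiers at the
#' 1 percent FDR threshold.
#'
#' @param proteomics named list of [OmicsMatrix] (the proteomics fractions).
#' @param transcripts optional transcriptomics [OmicsMatrix].
#' @param annotation named list: pathway id -> character vector of members.
#' @param minPerSide membership floor per dataset (default 2).
#' @param fdrThreshold significance threshold on q (default 0.01).
#' @param qMethod q-value method, see [qValues()].
#' @return An [EnrichmentResults-class] object.
#' @examples
#' study <- simulateStudy(SimStudyConfig(seed = 3, n_features = 300,
#'                                       datasets = c("TL", "EL")),
#'                        nPathways = 20)
#' enrichPathways(study$proteomics, study$transcripts, study$annotation)
#' @export
enrichPathways <- function(proteomics, transcripts = NULL, annotation,
                           minPerSide = 2L, fdrThreshold = 0.01,
                           qMethod = "BH") {
  stopifnot(is.list(proteomics), length(proteomics) >= 1)
  if (is.null(names(proteomics)))
    names(proteomics) <- vapply(proteomics, datasetTag, "")
  tstats <- lapply(proteomics, function(m) {
    st <- geneTStats(m)
    stats::setNames(st$t, st$gene_id)
  })
  protTags <- names(tstats)
  if (!is.null(transcripts)) {
    st <- geneTStats(transcripts)
    tstats[[datasetTag(transcripts)]] <- stats::setNames(st$t, st$gene_id)
  }
  profile <- rankDatasets(tstats, proteomicsTags = protTags)
  C <- .rankCorrelation(profile)
  ids <- names(annotation)
  D <- length(profile$datasets)
  scoreMat <- matrix(NA_real_, length(ids), D,
                     dimnames = list(ids, profile$datasets))
  kMat <- matrix(0L, length(ids), D, dimnames = list(ids, profile$datasets))
  T2 <- p <- rep(NA_real_, length(ids))
  skipReason <- character(length(ids))
  for (i in seq_along(ids)) {
    mem <- annotation[[i]]
    res <- manovaEnrichmentTest(profile, mem, minPerSide, rankCor = C)
    kMat[i, ] <- res$k
    if (res$skipped) { skipReason[i] <- res$reason; next }
    scoreMat[i, ] <- categoryScores(profile, mem)
    T2[i] <- res$T2; p[i] <- res$p
  }
  tested <- !nzchar(skipReason)
  q <- rep(NA_real_, length(ids))
  q[tested] <- qValues(p[tested], method = qMethod)
  tiers <- classifyTiers(q, fdrThreshold = fdrThreshold)
  res <- DataFrame(pathway_id = ids, name = ids,
                   k = I(kMat), score = I(scoreMat),
                   T2 = T2, p = p, q = q,
                   significant = tiers$significant, tier = tiers$tier)
  new("EnrichmentResults",
      results = res[tested, ],
      skipped = DataFrame(pathway_id = ids[!tested],
                          reason = skipReason[!tested]),
      datasets = profile$datasets)
}
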