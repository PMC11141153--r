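# Small builders shared across test files.

makeOmics <- function(values, groups = rep(c("AF", "sham"),
                                           each = ncol(values) / 2),
                      tag = "TL") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  OmicsMatrix(values, groups, tag)
}

# Figure-legend replicate activities (nmol/min/mg), as printed.
assayReplicates <- list(
  beta_gal  = list(af = c(2.64, 3.02, 3.26), sham = c(2.48, 2.57, 5.68)),
  hex_a     = list(af = c(6.66, 6.74, 6.87), sham = c(5.4, 10.61, 10.78)),
  hex_b     = list(af = c(1.52, 1.66, 1.73), sham = c(1.5, 1.62, 2.23)))

# Independent pooled two-sample t computed from first principles; used as the
# oracle against the package implementations.
oracleT <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2,
       p = 2 * pt(abs(t), n1 + n2 - 2, lower.tail = FALSE))
}

# Brute-force permutation-FDR volcano: loops over all balanced splits and
# candidate cutoffs with scalar arithmetic only. Independent of the
# vectorized implementation.
oracleVolcano <- function(values, isA, s0, fdrTarget = 0.05) {
  dmod <- function(cols) {
    apply(values, 1L, function(row) {
      a <- row[cols][!is.na(row[cols])]
      b <- row[!seq_along(row) %in% cols]
      b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) return(NA_real_)
      se <- sqrt((((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                    (length(a) + length(b) - 2)) *
                   (1 / length(a) + 1 / length(b)))
      (mean(a) - mean(b)) / (se + s0)
    })
  }
  obs <- abs(dmod(which(isA)))
  splits <- combn(length(isA), sum(isA))
  permAbs <- lapply(seq_len(ncol(splits)), function(j) {
    d <- abs(dmod(splits[, j]))
    d[!is.na(d)]
  })
  cand <- sort(unique(obs[is.finite(obs)]))
  fdr <- sapply(cand, function(cc) {
    false <- median(sapply(permAbs, function(d) sum(d >= cc)))
    false / max(1, sum(obs >= cc, na.rm = TRUE))
  })
  fdrMono <- cummin(fdr)
  sel <- which(fdrMono <= fdrTarget)
  cutoff <- if (length(sel)) cand[sel[1]] else Inf
  list(cand = cand, fdr = fdr, fdrMono = fdrMono, cutoff = cutoff,
       significant = !is.na(obs) & obs >= cutoff)
}
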