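#' Configuration for the synthetic multi-omics study generator
#'
#' Collects and validates the parameters shared by [simulateProteomics()],
#' [simulateTranscriptCounts()], [simulatePathwayAnnotation()] and
#' [simulateStudy()]. Defaults mirror a 3-vs-3 biological-replicate design
#' over three sub-cellular fractions (tissue lysate, endolysosome,
#' mitochondria) plus one transcriptomics dataset.
#'
#' @param seed integer seed; identical config + seed reproduce identical
#'   output bit-for-bit.
#' @param n_features number of features (proteins or genes).
#' @param n_per_group biological replicates per condition (>= 2).
#' @param datasets character vector of dataset tags to simulate.
#' @param frac_regulated proportion of features (and of pathways) carrying a
#'   true group effect.
#' @param effect_log2 true AF-vs-sham shift, in log2 units.
#' @param missing_rate overall proportion of missing intensity cells, in
#'   \code{[0, 1)}.
#' @param missing_mode \code{"random"} (missing completely at random) or
#'   \code{"intensity"} (left-censoring: missing probability is logistic in
#'   decreasing log2 intensity, calibrated to \code{missing_rate} overall).
#' @param dispersion negative-binomial size parameter for transcript counts;
#'   variance = mu + mu^2 / dispersion, so large values approach Poisson.
#' @param sigma_range range of per-feature log2 residual SDs (uniform draw).
#' @param baseline_mean,baseline_sd normal distribution of per-feature
#'   baseline log2 intensities.
#' @return A validated \code{SimStudyConfig} list.
#' @export
SimStudyConfig <- function(seed = 1L, n_features = 1000L, n_per_group = 3L,
                           datasets = c("TL", "EL", "Mito"),
                           frac_regulated = 0.1, effect_log2 = 2,
                           missing_rate = 0.1,
                           missing_mode = c("random", "intensity"),
                           dispersion = 10,
                           sigma_range = c(0.2, 0.8),
                           baseline_mean = 23, baseline_sd = 2) {
  missing_mode <- match.arg(missing_mode)
  if (n_features < 1) stop("n_features must be positive")
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  .checkProportion(frac_regulated, "frac_regulated")
  .checkProportion(missing_rate, "missing_rate", allowOne = FALSE)
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (length(sigma_range) != 2L || any(sigma_range <= 0) ||
      sigma_range[1] > sigma_range[2])
    stop("sigma_range must be an increasing pair of positive values")
  structure(list(seed = as.integer(seed), n_features = as.integer(n_features),
                 n_per_group = as.integer(n_per_group), datasets = datasets,
                 frac_regulated = frac_regulated, effect_log2 = effect_log2,
                 missing_rate = missing_rate, missing_mode = missing_mode,
                 dispersion = dispersion, sigma_range = sigma_range,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd),
            class = "SimStudyConfig")
}

.featureIds <- function(n) sprintf("G%05d", seq_len(n))

.pickRegulated <- function(config) {
  nReg <- round(config$frac_regulated * config$n_features)
  ids <- .featureIds(config$n_features)
  reg <- sort(sample(ids, nReg))
  stats::setNames(rep(config$effect_log2, nReg), reg)
}

.applyMissing <- function(values, config) {
  if (config$missing_rate == 0)
    return(values)
  z <- log2(values)
  p <- if (config$missing_mode == "random") {
    matrix(config$missing_rate, nrow(values), ncol(values))
  } else {
    a <- .calibrateLogisticIntercept(as.vector(z), config$missing_rate)
    stats::plogis(a - z)
  }
  values[stats::runif(length(values)) < p] <- NA
  values
}

#' Simulate a label-free proteomics intensity matrix with known ground truth
#'
#' Log2 intensities are normal with feature-specific baselines and residual
#' SDs; regulated features are shifted by \code{effect_log2} in the AF group.
#' Values are emitted on the raw (2^x) scale so the downstream log2 step is
#' exercised, and missingness is applied per \code{missing_mode}.
#'
#' @param config a [SimStudyConfig()].
#' @param dataset dataset tag for the result (drives the derived seed, so
#'   each fraction of one study is distinct but reproducible).
#' @param regulated optional named numeric vector (feature id -> signed log2
#'   effect) overriding the random choice of regulated features; used by
#'   [simulateStudy()] to share one truth across fractions.
#' @return \code{list(matrix = OmicsMatrix, truth = list(regulated_features))}.
#' @examples
#' sim <- simulateProteomics(SimStudyConfig(seed = 1, n_features = 50))
#' sim$matrix
#' @export
simulateProteomics <- function(config, dataset = "TL", regulated = NULL) {
  stopifnot(inherits(config, "SimStudyConfig"))
  set.seed(deriveSeed(config$seed, paste0("proteomics:", dataset)))
  n <- config$n_features
  nps <- config$n_per_group
  ids <- .featureIds(n)
  if (is.null(regulated)) regulated <- .pickRegulated(config)
  effect <- stats::setNames(rep(0, n), ids)
  effect[names(regulated)] <- regulated
  mu <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  sigma <- stats::runif(n, config$sigma_range[1], config$sigma_range[2])
  groups <- rep(c("AF", "sham"), each = nps)
  shift <- outer(effect, as.numeric(groups == "AF"))
  z <- mu + shift + matrix(stats::rnorm(n * 2 * nps), n) * sigma
  values <- 2^z
  dimnames(values) <- list(ids, sprintf("%s_%s_%d", dataset, groups,
                                        rep(seq_len(nps), 2)))
  values <- .applyMissing(values, config)
  om <- OmicsMatrix(values, groups, dataset)
  list(matrix = om, truth = list(regulated_features = regulated))
}

#' Simulate an overdispersed transcript count matrix
#'
#' Negative-binomial counts with per-sample library-size factors; regulated
#' genes are shifted multiplicatively by \code{2^effect_log2} in the AF group.
#'
#' @inheritParams simulateProteomics
#' @param libSizeFactors optional numeric vector of per-sample factors
#'   (default: drawn uniformly from \code{[0.7, 1.4]}).
#' @return \code{list(matrix = OmicsMatrix, truth = list(regulated_features))}.
#' @export
simulateTranscriptCounts <- function(config, dataset = "RNA",
                                     regulated = NULL,
                                     libSizeFactors = NULL) {
  stopifnot(inherits(config, "SimStudyConfig"))
  if (config$dispersion <= 0) stop("dispersion must be > 0")
  set.seed(deriveSeed(config$seed, paste0("transcripts:", dataset)))
  n <- config$n_features
  nps <- config$n_per_group
  ids <- .featureIds(n)
  if (is.null(regulated)) regulated <- .pickRegulated(config)
  effect <- stats::setNames(rep(0, n), ids)
  effect[names(regulated)] <- regulated
  groups <- rep(c("AF", "sham"), each = nps)
  if (is.null(libSizeFactors))
    libSizeFactors <- stats::runif(2 * nps, 0.7, 1.4)
  baseMean <- exp(stats::rnorm(n, log(200), 1.2))
  mu <- outer(baseMean, libSizeFactors) *
    2^outer(effect, as.numeric(groups == "AF"))
  counts <- matrix(stats::rnbinom(n * 2 * nps, mu = as.vector(mu),
                                  size = config$dispersion), n)
  dimnames(counts) <- list(ids, sprintf("%s_%s_%d", dataset, groups,
                                        rep(seq_len(nps), 2)))
  om <- OmicsMatrix(counts, groups, dataset, valueKind = "count")
  list(matrix = om, truth = list(regulated_features = regulated,
                                 lib_size_factors = libSizeFactors))
}

#' Simulate a pathway membership annotation with planted regulated pathways
#'
#' Background pathways sample members uniformly without replacement from the
#' feature universe; planted regulated pathways draw all members from the
#' regulated feature set, so every member carries the common signed effect.
#'
#' @param config a [SimStudyConfig()]; \code{frac_regulated} also sets the
#'   fraction of planted pathways.
#' @param nPathways total number of pathways.
#' @param sizeRange integer pair: min and max members per pathway.
#' @param universe character vector of feature ids (default: the config's
#'   feature id universe).
#' @param regulated named numeric vector of regulated features to plant from
#'   (default: none planted).
#' @return \code{list(annotation = named list of member-id vectors,
#'   truth = list(regulated_pathways))}.
#' @export
simulatePathwayAnnotation <- function(config, nPathways = 100,
                                      sizeRange = c(5, 30),
                                      universe = .featureIds(config$n_features),
                                      regulated = NULL) {
  stopifnot(inherits(config, "SimStudyConfig"))
  if (length(universe) == 0) stop("feature universe is empty")
  if (sizeRange[2] > length(universe))
    stop("size_range exceeds the size of the feature universe")
  set.seed(deriveSeed(config$seed, "pathways"))
  if (nPathways == 0)
    return(list(annotation = stats::setNames(list(), character()),
                truth = list(regulated_pathways = numeric())))
  nPlanted <- if (is.null(regulated) || length(regulated) < sizeRange[1]) 0 else
    round(config$frac_regulated * nPathways)
  sizes <- sample(seq(sizeRange[1], sizeRange[2]), nPathways, replace = TRUE)
  ann <- vector("list", nPathways)
  names(ann) <- sprintf("PW%04d", seq_len(nPathways))
  shifts <- numeric()
  for (i in seq_len(nPathways)) {
    if (i <= nPlanted) {
      k <- min(sizes[i], length(regulated))
      ann[[i]] <- sort(sample(names(regulated), k))
      shifts[names(ann)[i]] <- sign(regulated[[ann[[i]][1]]]) *
        abs(config$effect_log2)
    } else {
      ann[[i]] <- sort(sample(universe, sizes[i]))
    }
  }
  list(annotation = ann, truth = list(regulated_pathways = shifts))
}

#' Simulate a coherent multi-dataset study
#'
#' One shared set of regulated features drives every proteomics fraction and
#' the transcript dataset; pathway annotation is planted on that same set.
#' This is the canonical input for testing the integrated rank-enrichment
#' analysis with known truth.
#'
#' @inheritParams simulatePathwayAnnotation
#' @param rnaDataset tag for the transcript dataset (\code{NULL} to skip).
#' @return list with \code{proteomics} (named list of OmicsMatrix),
#'   \code{transcripts} (OmicsMatrix or NULL), \code{annotation},
#'   \code{truth}.
#' @export
simulateStudy <- function(config, nPathways = 100, sizeRange = c(5, 30),
                          rnaDataset = "RNA") {
  stopifnot(inherits(config, "SimStudyConfig"))
  set.seed(deriveSeed(config$seed, "study"))
  regulated <- .pickRegulated(config)
  prot <- lapply(config$datasets, function(d)
    simulateProteomics(config, dataset = d, regulated = regulated)$matrix)
  names(prot) <- config$datasets
  rna <- if (is.null(rnaDataset)) NULL else
    simulateTranscriptCounts(config, dataset = rnaDataset,
                             regulated = regulated)$matrix
  pw <- simulatePathwayAnnotation(config, nPathways, sizeRange,
                                  regulated = regulated)
  list(proteomics = prot, transcripts = rna, annotation = pw$annotation,
       truth = list(regulated_features = regulated,
                    regulated_pathways = pw$truth$regulated_pathways))
}

#' Specification of a synthetic electron micrograph
#'
#' @param width,height image size in pixels.
#' @param nm_per_px physical calibration.
#' @param n_granules number of dark quasi-circular glycogen granules.
#' @param granule_radius_px mean and SD of granule radii, pixels.
#' @param granule_darkness intensity decrement of a granule centre relative
#'   to the local background (0-1 scale).
#' @param background_texture_sd SD of the smooth cytosolic background texture.
#' @param n_organelle_blobs number of larger bright elliptical organelles.
#' @param noise_sd SD of per-pixel Gaussian acquisition noise.
#' @param seed integer seed.
#' @return A validated \code{GranuleImageSpec} list.
#' @export
GranuleImageSpec <- function(width = 512L, height = 512L, nm_per_px = 2,
                             n_granules = 50L,
                             granule_radius_px = c(mean = 4, sd = 0.5),
                             granule_darkness = 0.35,
                             background_texture_sd = 0.03,
                             n_organelle_blobs = 3L, noise_sd = 0.02,
                             seed = 1L) {
  if (width < 8 || height < 8) stop("image too small")
  if (nm_per_px <= 0) stop("nm_per_px must be positive")
  if (n_granules < 0) stop("n_granules must be >= 0")
  if (granule_radius_px[1] <= 0) stop("granule radius must be positive")
  structure(list(width = as.integer(width), height = as.integer(height),
                 nm_per_px = nm_per_px, n_granules = as.integer(n_granules),
                 granule_radius_px = granule_radius_px,
                 granule_darkness = granule_darkness,
                 background_texture_sd = background_texture_sd,
                 n_organelle_blobs = as.integer(n_organelle_blobs),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "GranuleImageSpec")
}

# Anti-aliased disk coverage subtracted from (or added to) img in place.
.stampDisk <- function(img, cx, cy, r, delta) {
  x0 <- max(1L, floor(cx - r - 1)); x1 <- min(ncol(img), ceiling(cx + r + 1))
  y0 <- max(1L, floor(cy - r - 1)); y1 <- min(nrow(img), ceiling(cy + r + 1))
  xs <- x0:x1; ys <- y0:y1
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
  cov <- pmin(pmax(r + 0.5 - d, 0), 1)
  img[ys, xs] <- img[ys, xs] + delta * cov
  img
}

#' Simulate an electron micrograph with planted glycogen granules
#'
#' The image is a textured cytosolic background plus bright irregular
#' organelle ellipses, \code{n_granules} dark anti-aliased disks placed
#' without overlap (a minimum gap of 2 px between granule rims), and
#' per-pixel Gaussian noise. Ground truth records the exact granule centres
#' and radii (1-based pixel coordinates, x = column) and the bounding boxes
#' of the organelle blobs so generated ROIs can avoid them.
#'
#' @param spec a [GranuleImageSpec()].
#' @return \code{list(image = EMImage, truth = list(granules = data.frame(x,
#'   y, radius), organelle_boxes = data.frame(x0, y0, width, height)))} with
#'   organelle boxes in the 0-based half-open ROI convention.
#' @export
simulateEMImage <- function(spec) {
  stopifnot(inherits(spec, "GranuleImageSpec"))
  set.seed(spec$seed)
  w <- spec$width; h <- spec$height
  base <- matrix(0.62, h, w)
  if (spec$background_texture_sd > 0) {
    tex <- matrix(stats::rnorm(h * w), h, w)
    sigmaTex <- min(6, (min(w, h) - 3) / 7)  # keep the kernel inside the image
    tex <- EBImage::imageData(EBImage::gblur(EBImage::as.Image(tex),
                                             sigma = sigmaTex))
    base <- base + tex * (spec$background_texture_sd / stats::sd(tex))
  }
  blobs <- data.frame(x0 = integer(), y0 = integer(),
                      width = integer(), height = integer())
  for (b in seq_len(spec$n_organelle_blobs)) {
    ax <- stats::runif(1, min(25, w / 8), min(60, w / 4))
    ay <- stats::runif(1, min(20, h / 8), min(45, h / 4))
    cx <- stats::runif(1, ax + 2, w - ax - 1)
    cy <- stats::runif(1, ay + 2, h - ay - 1)
    th <- stats::runif(1, 0, pi)
    xs <- seq_len(w); ys <- seq_len(h)
    xr <- outer(rep(1, h), xs - cx); yr <- outer(ys - cy, rep(1, w))
    u <- (xr * cos(th) + yr * sin(th)) / ax
    v <- (-xr * sin(th) + yr * cos(th)) / ay
    base <- base + 0.16 * pmin(pmax(1.05 - sqrt(u^2 + v^2), 0) / 0.1, 1)
    blobs <- rbind(blobs, data.frame(
      x0 = max(0L, floor(cx - ax) - 1L), y0 = max(0L, floor(cy - ay) - 1L),
      width = min(w, ceiling(2 * ax) + 2L), height = min(h, ceiling(2 * ay) + 2L)))
  }
  rmean <- spec$granule_radius_px[[1]]
  rsd <- if (length(spec$granule_radius_px) > 1) spec$granule_radius_px[[2]] else 0
  gx <- gy <- gr <- numeric(0)
  maxTries <- 200L * max(1L, spec$n_granules)
  tries <- 0L
  while (length(gx) < spec$n_granules) {
    tries <- tries + 1L
    if (tries > maxTries)
      stop("image too small to place the requested granules without overlap")
    r <- max(1, stats::rnorm(1, rmean, rsd))
    x <- stats::runif(1, r + 2, w - r - 1)
    y <- stats::runif(1, r + 2, h - r - 1)
    if (length(gx) &&
        any(sqrt((gx - x)^2 + (gy - y)^2) < gr + r + 2)) next
    gx <- c(gx, x); gy <- c(gy, y); gr <- c(gr, r)
  }
  for (i in seq_along(gx))
    base <- .stampDisk(base, gx[i], gy[i], gr[i], -spec$granule_darkness)
  if (spec$noise_sd > 0)
    base <- base + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
  base <- pmin(pmax(base, 0), 1)
  img <- EMImage(base, nmPerPx = spec$nm_per_px,
                 imageId = sprintf("sim%08d", spec$seed))
  list(image = img,
       truth = list(granules = data.frame(x = gx, y = gy, radius = gr),
                    organelle_boxes = blobs))
}

#' Generate rectangular ROIs avoiding organelle regions
#'
#' Mirrors manual box selection on micrographs: axis-aligned boxes are drawn
#' uniformly inside the image and rejected when they intersect any of the
#' supplied avoid-boxes (typically the organelle bounding boxes from
#' [simulateEMImage()] ground truth). Coordinates are 0-based, half-open.
#'
#' @param width,height image size in pixels.
#' @param avoid data.frame with columns x0, y0, width, height.
#' @param n number of ROIs (5-7 per image is typical).
#' @param roiWidth,roiHeight ROI size in pixels.
#' @param seed integer seed.
#' @return data.frame(x0, y0, width, height).
#' @export
generateRois <- function(width, height, avoid = NULL, n = 6,
                         roiWidth = 120, roiHeight = 120, seed = 1L) {
  set.seed(seed)
  out <- data.frame(x0 = integer(), y0 = integer(),
                    width = integer(), height = integer())
  intersects <- function(x0, y0) {
    if (is.null(avoid) || nrow(avoid) == 0) return(FALSE)
    any(x0 < avoid$x0 + avoid$width & x0 + roiWidth > avoid$x0 &
        y0 < avoid$y0 + avoid$height & y0 + roiHeight > avoid$y0)
  }
  tries <- 0L
  while (nrow(out) < n) {
    tries <- tries + 1L
    if (tries > 2000L * n)
      stop("could not place the requested ROIs outside the avoid regions")
    x0 <- sample.int(width - roiWidth + 1L, 1L) - 1L
    y0 <- sample.int(height - roiHeight + 1L, 1L) - 1L
    if (!intersects(x0, y0))
      out <- rbind(out, data.frame(x0 = x0, y0 = y0, width = roiWidth,
                                   height = roiHeight))
  }
  out
}

#' Simulate a fluorometric enzyme-assay plate
#'
#' Standards are a linear response to known free 4-MU amounts; unknown wells
#' carry the responses implied by the true activities, incubation time and
#' protein mass (released 4-MU = activity x time x mass). Gaussian response
#' noise is optional, so at \code{noiseSd = 0} back-calculation through
#' [enzymeActivity()] recovers the true activities exactly.
#'
#' @param trueActivities named numeric vector, nmol/min/mg per sample.
#' @param curveSlope,curveIntercept true standard-curve parameters
#'   (fluorescence per nmol, fluorescence at zero).
#' @param noiseSd SD of response noise (fluorescence units).
#' @param seed integer seed.
#' @param timeMin incubation time, minutes.
#' @param proteinMg protein mass per well, mg.
#' @param standardAmounts known 4-MU amounts for the standards, nmol.
#' @return data.frame(well, role, sample_id, known_amount, response,
#'   time_min, protein_mg).
#' @export
simulateAssayPlate <- function(trueActivities, curveSlope = 1000,
                               curveIntercept = 50, noiseSd = 0, seed = 1L,
                               timeMin = 60, proteinMg = 1,
                               standardAmounts = seq(0, 5, length.out = 8)) {
  if (curveSlope == 0) stop("curveSlope must be non-zero")
  if (timeMin <= 0 || any(proteinMg <= 0))
    stop("incubation time and protein mass must be positive")
  set.seed(seed)
  nS <- length(standardAmounts)
  nU <- length(trueActivities)
  proteinMg <- rep(proteinMg, length.out = nU)
  released <- trueActivities * timeMin * proteinMg
  resp <- curveIntercept + curveSlope * c(standardAmounts, released)
  if (noiseSd > 0) resp <- resp + stats::rnorm(nS + nU, 0, noiseSd)
  ids <- names(trueActivities)
  if (is.null(ids)) ids <- sprintf("U%02d", seq_len(nU))
  data.frame(
    well = sprintf("W%02d", seq_len(nS + nU)),
    role = c(rep("standard", nS), rep("unknown", nU)),
    sample_id = c(rep(NA_character_, nS), ids),
    known_amount = c(standardAmounts, rep(NA_real_, nU)),
    response = resp,
    time_min = c(rep(NA_real_, nS), rep(timeMin, nU)),
    protein_mg = c(rep(NA_real_, nS), proteinMg),
    stringsAsFactors = FALSE)
}
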