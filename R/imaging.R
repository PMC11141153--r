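#' Configuration of the automated granule-counting pipeline
#'
#' The pipeline parameters mirror the stages of the counting algorithm:
#' Gaussian smoothing, a grayscale minimum filter accentuating dark areas, a
#' dark-foreground binarization threshold, and area rules converting
#' connected components to granule counts. The defaults are tuned for
#' granules of roughly 4 px radius on a mid-gray background; they are
#' fixtures to be adjusted by visual inspection on real micrographs.
#'
#' @param gaussian_sigma Gaussian blur SD in pixels (0 disables).
#' @param min_filter_size square minimum-filter window, odd, >= 1
#'   (1 disables).
#' @param threshold binarization threshold on the [0, 1] intensity scale
#'   (foreground strictly below), or \code{"otsu"} to compute it from the
#'   sub-image histogram. The fixed default separates granule-dark pixels
#'   from mid-gray cytosol; Otsu is preferable only when granules are dense
#'   enough to form a clear second histogram mode.
#' @param min_area smallest component area (px^2) counted as a granule.
#' @param single_granule_area area (px^2) of one granule; larger components
#'   count \code{max(1, floor(area / single_granule_area))}.
#' @param connectivity pixel connectivity, 4 or 8 (default 8).
#' @return A validated \code{GranuleConfig} list.
#' @export
GranuleConfig <- function(gaussian_sigma = 1, min_filter_size = 3L,
                          threshold = 0.45, min_area = 15,
                          single_granule_area = 110, connectivity = 8L) {
  if (gaussian_sigma < 0) stop("gaussian_sigma must be >= 0")
  if (min_filter_size < 1 || min_filter_size %% 2 == 0)
    stop("min_filter_size must be odd and >= 1")
  if (!identical(threshold, "otsu") &&
      (!is.numeric(threshold) || threshold < 0 || threshold > 1))
    stop("threshold must be 'otsu' or a number in [0, 1]")
  if (min_area < 1) stop("min_area must be >= 1")
  if (single_granule_area < min_area)
    stop("single_granule_area must be >= min_area")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  structure(list(gaussian_sigma = gaussian_sigma,
                 min_filter_size = as.integer(min_filter_size),
                 threshold = threshold, min_area = min_area,
                 single_granule_area = single_granule_area,
                 connectivity = as.integer(connectivity)),
            class = "GranuleConfig")
}

#' Crop rectangular ROIs out of a micrograph
#'
#' Rectangles use 0-based, half-open pixel coordinates: \code{(x0, y0,
#' width, height)} selects columns \code{x0 .. x0 + width - 1} and rows
#' \code{y0 .. y0 + height - 1} (0-based). Overlapping ROIs are permitted
#' and cropped independently.
#'
#' @param image an [EMImage].
#' @param rois data.frame with columns x0, y0, width, height.
#' @return list of pixel matrices, one per ROI, each carrying its rectangle
#'   in attribute \code{"roi"}.
#' @export
cropRois <- function(image, rois) {
  stopifnot(is(image, "EMImage"),
            all(c("x0", "y0", "width", "height") %in% colnames(rois)))
  px <- image@pixels
  W <- ncol(px); H <- nrow(px)
  lapply(seq_len(nrow(rois)), function(i) {
    r <- rois[i, ]
    if (r$x0 < 0 || r$y0 < 0 || r$width < 1 || r$height < 1 ||
        r$x0 + r$width > W || r$y0 + r$height > H)
      stop(sprintf("ROI %d out of image bounds", i))
    out <- px[(r$y0 + 1):(r$y0 + r$height), (r$x0 + 1):(r$x0 + r$width),
              drop = FALSE]
    attr(out, "roi") <- as.list(r)
    out
  })
}

#' Smooth and accentuate dark areas of a cropped ROI
#'
#' Gaussian blur followed by a square grayscale minimum filter; with
#' \code{gaussian_sigma = 0} and \code{min_filter_size = 1} the image is
#' returned unchanged.
#'
#' @param roi pixel matrix in [0, 1].
#' @param config a [GranuleConfig()].
#' @return filtered pixel matrix, same shape.
#' @export
preprocessRoi <- function(roi, config) {
  stopifnot(inherits(config, "GranuleConfig"))
  out <- roi
  if (config$gaussian_sigma > 0)
    out <- EBImage::imageData(EBImage::gblur(EBImage::as.Image(out),
                                             sigma = config$gaussian_sigma))
  if (config$min_filter_size > 1)
    out <- EBImage::imageData(EBImage::erode(
      EBImage::as.Image(out),
      EBImage::makeBrush(config$min_filter_size, shape = "box")))
  out
}

#' Binarize a filtered ROI into a dark-foreground mask
#'
#' Foreground pixels are those strictly below the threshold (granules are
#' dark). Under \code{"otsu"} the threshold is computed from the sub-image
#' histogram; a degenerate single-valued histogram yields an empty mask with
#' a warning.
#'
#' @param roi filtered pixel matrix in [0, 1].
#' @param config a [GranuleConfig()].
#' @return logical mask matrix.
#' @export
binarizeRoi <- function(roi, config) {
  stopifnot(inherits(config, "GranuleConfig"))
  thr <- config$threshold
  if (identical(thr, "otsu")) {
    if (max(roi) - min(roi) < .Machine$double.eps * 4) {
      warning("degenerate histogram under otsu: empty foreground")
      return(matrix(FALSE, nrow(roi), ncol(roi)))
    }
    thr <- EBImage::otsu(EBImage::as.Image(roi))
  }
  roi < thr
}

# Connected-component labels; bwlabel is 4-connective, so 8-connectivity
# merges labels that touch diagonally (union-find over diagonal adjacencies).
.labelComponents <- function(mask, connectivity = 8L) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::as.Image(mask)))
  nlab <- max(lab)
  if (connectivity == 4L || nlab < 2) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  H <- nrow(lab); W <- ncol(lab)
  for (dd in list(c(1, 1), c(1, -1))) {
    dy <- dd[1]; dx <- dd[2]
    ys <- seq_len(H - 1)
    xs <- if (dx == 1) seq_len(W - 1) else 2:W
    a <- lab[ys, xs, drop = FALSE]
    b <- lab[ys + dy, xs + dx, drop = FALSE]
    pair <- which(a > 0 & b > 0 & a != b)
    for (idx in pair) {
      ra <- find(a[idx]); rb <- find(b[idx])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nlab), find, 0L)
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

#' Count granules in a binary mask
#'
#' Connected components at the configured connectivity; components smaller
#' than \code{min_area} are discarded, a component up to
#' \code{single_granule_area} counts one granule, and a larger merged blob
#' counts the maximum number of single granules that fit by area:
#' \code{max(1, floor(area / single_granule_area))}.
#'
#' @param mask logical matrix.
#' @param config a [GranuleConfig()].
#' @return list(count, components = data.frame(label, area, count)).
#' @export
countGranules <- function(mask, config) {
  stopifnot(inherits(config, "GranuleConfig"), is.logical(mask))
  lab <- .labelComponents(mask, config$connectivity)
  if (max(lab) == 0)
    return(list(count = 0L,
                components = data.frame(label = integer(), area = numeric(),
                                        count = integer())))
  area <- tabulate(lab[lab > 0])
  keep <- which(area >= config$min_area)
  cnt <- pmax(1L, as.integer(floor(area[keep] / config$single_granule_area)))
  list(count = as.integer(sum(cnt)),
       components = data.frame(label = keep, area = area[keep], count = cnt))
}

#' Granule density per physical area
#'
#' @param count granule count.
#' @param areaPx ROI area in px^2.
#' @param nmPerPx calibration, nanometres per pixel.
#' @param unit \code{"per_nm2"} (default, mirroring how such counts are
#'   usually reported) or \code{"per_um2"}.
#' @return density, granules per nm^2 or per um^2.
#' @export
granuleDensity <- function(count, areaPx, nmPerPx,
                           unit = c("per_nm2", "per_um2")) {
  unit <- match.arg(unit)
  if (areaPx <= 0) stop("ROI area must be positive")
  if (nmPerPx <= 0) stop("nmPerPx must be positive")
  d <- count / (areaPx * nmPerPx^2)
  if (unit == "per_um2") d <- d * 1e6
  d
}

#' Run the full automated granule count on an image's ROIs
#'
#' @param image an [EMImage].
#' @param rois data.frame(x0, y0, width, height), 0-based half-open.
#' @param config a [GranuleConfig()].
#' @param unit density unit, see [granuleDensity()].
#' @return data.frame(image_id, roi, count, area_px2, area_nm2, density,
#'   method).
#' @export
countGranulesInImage <- function(image, rois, config = GranuleConfig(),
                                 unit = "per_nm2") {
  crops <- cropRois(image, rois)
  out <- lapply(seq_along(crops), function(i) {
    filt <- preprocessRoi(crops[[i]], config)
    mask <- binarizeRoi(filt, config)
    cnt <- countGranules(mask, config)$count
    areaPx <- nrow(crops[[i]]) * ncol(crops[[i]])
    data.frame(image_id = image@imageId, roi = i, count = cnt,
               area_px2 = areaPx, area_nm2 = areaPx * image@nmPerPx^2,
               density = granuleDensity(cnt, areaPx, image@nmPerPx, unit),
               method = "automated", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare granule densities between conditions
#'
#' Two-sided pooled two-sample t-test on per-observation densities, at the
#' chosen aggregation level (every ROI as an observation, or per-animal mean
#' densities).
#'
#' @param densities data.frame with columns \code{density}, \code{group},
#'   and (for animal-level aggregation) \code{animal_id}.
#' @param level \code{"roi"} or \code{"animal"}.
#' @return a \code{TTestResult} list, see [twoSampleT()], plus group means
#'   and SDs.
#' @export
compareGranuleDensities <- function(densities, level = c("roi", "animal")) {
  level <- match.arg(level)
  stopifnot(all(c("density", "group") %in% colnames(densities)))
  if (level == "animal") {
    stopifnot("animal_id" %in% colnames(densities))
    agg <- stats::aggregate(density ~ group + animal_id, densities, mean)
  } else agg <- densities
  gs <- unique(agg$group)
  if (length(gs) != 2L) stop("exactly two groups are required")
  gs <- if ("AF" %in% gs) c("AF", setdiff(gs, "AF")) else sort(gs)
  a <- agg$density[agg$group == gs[1]]
  b <- agg$density[agg$group == gs[2]]
  if (length(a) < 2 || length(b) < 2)
    stop("at least 2 observations per group are required")
  tt <- twoSampleT(a, b)
  c(tt, list(group_a = gs[1], group_b = gs[2],
             mean_a = mean(a), sd_a = stats::sd(a),
             mean_b = mean(b), sd_b = stats::sd(b)))
}
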