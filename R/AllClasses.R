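#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames colData rowData
#' @importFrom stats setNames
NULL

#' OmicsMatrix: a feature-by-sample quantitative omics assay
#'
#' Thin wrapper around \linkS4class{SummarizedExperiment} holding one assay
#' (\code{"exprs"}) of intensities or counts, with \code{NA} entries encoding
#' the missing-value mask, a two-level sample grouping (typically
#' \code{AF}/\code{sham}) in \code{colData()$group}, and a dataset tag
#' (\code{TL}, \code{EL}, \code{Mito} or \code{RNA}) in the object metadata.
#'
#' @slot ... see \linkS4class{SummarizedExperiment}.
#' @seealso [OmicsMatrix()], [omicsValues()], [missingMask()],
#'   [sampleGroups()], [datasetTag()]
#' @export
setClass("OmicsMatrix", contains = "SummarizedExperiment")

setValidity("OmicsMatrix", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  cd <- colData(object)
  if (!"group" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'group' column")
  else if (anyNA(cd$group))
    msg <- c(msg, "every sample must have a group label")
  tag <- metadata(object)$dataset_tag
  if (is.null(tag) || length(tag) != 1L || !nzchar(tag))
    msg <- c(msg, "metadata(object)$dataset_tag must be a single non-empty string")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "feature ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   \code{NA} marks a missing measurement.
#' @param groups character or factor of per-sample group labels, in column
#'   order (or named by sample id).
#' @param datasetTag single string tagging the dataset, e.g. \code{"TL"},
#'   \code{"EL"}, \code{"Mito"}, \code{"RNA"}.
#' @param valueKind \code{"intensity"} or \code{"count"}; counts are checked
#'   to be non-negative and integral.
#' @return An \linkS4class{OmicsMatrix}.
#' @examples
#' m <- matrix(2^rnorm(12, 23), 2, 6,
#'             dimnames = list(c("P1", "P2"), paste0("s", 1:6)))
#' om <- OmicsMatrix(m, rep(c("AF", "sham"), each = 3), "TL")
#' datasetTag(om)
#' @export
OmicsMatrix <- function(values, groups, datasetTag,
                        valueKind = c("intensity", "count")) {
  valueKind <- match.arg(valueKind)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("F%05d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%d", seq_len(ncol(values)))
  if (!is.null(names(groups))) groups <- groups[colnames(values)]
  if (length(groups) != ncol(values))
    stop("length(groups) must equal the number of samples")
  if (valueKind == "count") {
    v <- values[!is.na(values)]
    if (any(v < 0) || any(v != round(v)))
      stop("counts must be non-negative integers")
  }
  se <- SummarizedExperiment(
    assays = list(exprs = values),
    colData = DataFrame(group = as.character(groups),
                        row.names = colnames(values)))
  metadata(se)$dataset_tag <- as.character(datasetTag)
  metadata(se)$value_kind <- valueKind
  new("OmicsMatrix", se)
}

#' EMImage: a calibrated grayscale electron micrograph
#'
#' Pixel intensities are stored as a numeric matrix scaled to \code{[0, 1]}
#' (row = y, column = x); \code{nmPerPx} converts pixel lengths to nanometres.
#'
#' @slot pixels numeric matrix in \code{[0, 1]}.
#' @slot nmPerPx physical calibration, nanometres per pixel (> 0).
#' @slot imageId identifier.
#' @slot group condition label (\code{"AF"} or \code{"sham"}), may be \code{NA}.
#' @slot animalId biological-replicate identifier, may be \code{NA}.
#' @slot bitDepth nominal acquisition bit depth (8 or 16).
#' @export
setClass("EMImage",
  representation(pixels = "matrix", nmPerPx = "numeric", imageId = "character",
                 group = "character", animalId = "character",
                 bitDepth = "integer"),
  prototype(nmPerPx = 1, imageId = "img", group = NA_character_,
            animalId = NA_character_, bitDepth = 16L))

setValidity("EMImage", function(object) {
  msg <- character()
  if (length(object@nmPerPx) != 1L || !is.finite(object@nmPerPx) ||
      object@nmPerPx <= 0)
    msg <- c(msg, "nmPerPx must be a single positive number")
  px <- object@pixels
  if (!is.numeric(px) || length(px) == 0L)
    msg <- c(msg, "pixels must be a non-empty numeric matrix")
  else if (min(px) < 0 || max(px) > 1)
    msg <- c(msg, "pixel intensities must lie in [0, 1]")
  if (!object@bitDepth %in% c(8L, 16L))
    msg <- c(msg, "bitDepth must be 8 or 16")
  if (length(msg)) msg else TRUE
})

#' Construct an EMImage
#'
#' @param pixels numeric matrix of intensities in \code{[0, 1]}.
#' @param nmPerPx nanometres per pixel.
#' @param imageId,group,animalId identifiers (group/animal optional).
#' @param bitDepth nominal bit depth, 8 or 16.
#' @return An \linkS4class{EMImage}.
#' @export
EMImage <- function(pixels, nmPerPx = 1, imageId = "img",
                    group = NA_character_, animalId = NA_character_,
                    bitDepth = 16L) {
  new("EMImage", pixels = as.matrix(pixels), nmPerPx = as.numeric(nmPerPx),
      imageId = as.character(imageId), group = as.character(group),
      animalId = as.character(animalId), bitDepth = as.integer(bitDepth))
}

#' VolcanoResults: output of the permutation-FDR volcano procedure
#'
#' @slot results per-feature \link[S4Vectors]{DataFrame} with columns
#'   \code{feature_id}, \code{log2_fc}, \code{t_raw}, \code{d_mod},
#'   \code{p_raw}, \code{significant}, \code{direction}.
#' @slot cutoff selected cutoff on \code{|d_mod|} (\code{Inf} when no cutoff
#'   achieves the FDR target).
#' @slot fdrEst estimated FDR at the selected cutoff.
#' @slot nPermutations number of distinct relabelings used.
#' @slot exhaustive whether all distinct balanced splits were enumerated.
#' @slot config the volcano configuration used.
#' @export
setClass("VolcanoResults",
  representation(results = "DataFrame", cutoff = "numeric", fdrEst = "numeric",
                 nPermutations = "integer", exhaustive = "logical",
                 config = "list"))

#' EnrichmentResults: output of the multi-dataset rank-enrichment MANOVA
#'
#' @slot results per-pathway \link[S4Vectors]{DataFrame}: pathway id and name,
#'   per-dataset member counts and rank scores, \code{T2}, \code{p}, \code{q},
#'   \code{significant}, \code{tier}.
#' @slot skipped DataFrame of pathways excluded by the membership floor, with
#'   reasons.
#' @slot datasets dataset tags entering the joint test, in column order.
#' @export
setClass("EnrichmentResults",
  representation(results = "DataFrame", skipped = "DataFrame",
                 datasets = "character"))
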