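#' Accessors for OmicsMatrix and result containers
#'
#' @param x an object.
#' @name accessors
NULL

#' @describeIn accessors numeric value matrix (NA = missing).
#' @export
setGeneric("omicsValues", function(x) standardGeneric("omicsValues"))

#' @describeIn accessors logical matrix, TRUE where the value is missing.
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @describeIn accessors named character vector of per-sample group labels.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @describeIn accessors dataset tag string.
#' @export
setGeneric("datasetTag", function(x) standardGeneric("datasetTag"))

#' @describeIn accessors per-feature / per-pathway result table.
#' @export
setGeneric("resultsTable", function(x) standardGeneric("resultsTable"))

setMethod("omicsValues", "OmicsMatrix", function(x) assay(x, "exprs"))

setMethod("missingMask", "OmicsMatrix", function(x) is.na(assay(x, "exprs")))

setMethod("sampleGroups", "OmicsMatrix", function(x) {
  g <- as.character(colData(x)$group)
  names(g) <- colnames(x)
  g
})

setMethod("datasetTag", "OmicsMatrix", function(x) metadata(x)$dataset_tag)

setMethod("resultsTable", "VolcanoResults", function(x) x@results)
setMethod("resultsTable", "EnrichmentResults", function(x) x@results)

setMethod("show", "OmicsMatrix", function(object) {
  g <- table(sampleGroups(object))
  cat(sprintf("OmicsMatrix [%s] %d features x %d samples (%s); %.1f%% missing\n",
              datasetTag(object), nrow(object), ncol(object),
              paste(sprintf("%s=%d", names(g), g), collapse = ", "),
              100 * mean(missingMask(object))))
  invisible(object)
})

setMethod("show", "EMImage", function(object) {
  cat(sprintf("EMImage '%s' %dx%d px @ %.3g nm/px (%d-bit)%s\n",
              object@imageId, ncol(object@pixels), nrow(object@pixels),
              object@nmPerPx, object@bitDepth,
              if (is.na(object@group)) "" else paste0(", group ", object@group)))
  invisible(object)
})

setMethod("show", "VolcanoResults", function(object) {
  r <- object@results
  cat(sprintf(paste0("VolcanoResults: %d features, cutoff |d|>=%.4g ",
                     "(FDR est %.3g), %d significant (%d up / %d down); ",
                     "%d %s permutations\n"),
              nrow(r), object@cutoff, object@fdrEst, sum(r$significant),
              sum(r$direction == "up"), sum(r$direction == "down"),
              object@nPermutations,
              if (object@exhaustive) "exhaustive" else "sampled"))
  invisible(object)
})

setMethod("show", "EnrichmentResults", function(object) {
  r <- object@results
  cat(sprintf(paste0("EnrichmentResults over %s: %d pathways tested ",
                     "(%d skipped), %d significant at q<0.01\n"),
              paste(object@datasets, collapse = "/"), nrow(r),
              nrow(object@skipped), sum(r$significant)))
  invisible(object)
})
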