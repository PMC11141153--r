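#' Read and write wide feature-by-sample matrices with a design table
#'
#' The canonical table dialect is TSV (UTF-8, Unix newlines, '.' decimal):
#' first column the feature id, remaining columns one per sample; a missing
#' measurement is an empty cell. The design TSV carries sample_id, group and
#' dataset columns. \code{writeOmicsMatrix} / \code{readOmicsMatrix}
#' round-trip bit-exactly, including the missing mask.
#'
#' @param path matrix TSV path.
#' @param designPath design TSV path.
#' @param valueKind \code{"intensity"} or \code{"count"}; counts are
#'   validated as non-negative integers.
#' @return \code{readOmicsMatrix}: an [OmicsMatrix].
#' @export
readOmicsMatrix <- function(path, designPath,
                            valueKind = c("intensity", "count")) {
  valueKind <- match.arg(valueKind)
  lines <- readLines(path)
  if (!length(lines)) stop("empty matrix file")
  # trailing "\t" sentinel: strsplit drops exactly one trailing empty field,
  # so this preserves empty (missing) last cells while keeping ragged rows
  # detectable
  cells <- strsplit(paste0(lines, "\t"), "\t", fixed = TRUE)
  ncols <- length(cells[[1]])
  bad <- which(vapply(cells, length, 0L) != ncols)
  if (length(bad))
    stop(sprintf("ragged row at line %d of '%s'", bad[1], path))
  header <- cells[[1]][-1]
  ids <- vapply(cells[-1], `[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate feature id '%s' in '%s'", dup[1], path))
  vals <- matrix(NA_real_, length(ids), length(header),
                 dimnames = list(ids, header))
  for (i in seq_along(ids)) {
    row <- cells[[i + 1L]][-1]
    nz <- nzchar(row)
    v <- suppressWarnings(as.numeric(row[nz]))
    if (anyNA(v))
      stop(sprintf("non-numeric cell at line %d of '%s'", i + 1L, path))
    vals[i, nz] <- v
  }
  if (valueKind == "count") {
    v <- vals[!is.na(vals)]
    if (any(v < 0) || any(v != round(v)))
      stop(sprintf("negative or non-integer count in '%s'", path))
  }
  design <- utils::read.delim(designPath, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "group", "dataset") %in% colnames(design)))
  miss <- setdiff(header, design$sample_id)
  if (length(miss))
    stop(sprintf("sample '%s' missing from the design table", miss[1]))
  design <- design[match(header, design$sample_id), ]
  OmicsMatrix(vals, stats::setNames(design$group, design$sample_id),
              unique(design$dataset)[1], valueKind = valueKind)
}

#' @rdname readOmicsMatrix
#' @param x an [OmicsMatrix] to write.
#' @export
writeOmicsMatrix <- function(x, path, designPath = NULL) {
  stopifnot(is(x, "OmicsMatrix"))
  v <- omicsValues(x)
  fmt <- ifelse(is.na(v), "", vapply(v, format, "", digits = 17))
  dim(fmt) <- dim(v)
  lines <- c(paste(c("feature_id", colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i)
               paste(c(rownames(v)[i], fmt[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
  if (!is.null(designPath)) {
    design <- data.frame(sample_id = colnames(v),
                         group = unname(sampleGroups(x)),
                         dataset = datasetTag(x))
    utils::write.table(design, designPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read and write GMT pathway-membership files
#'
#' Standard GMT dialect: one pathway per line, tab-separated fields name,
#' description, then member ids. Members are de-duplicated per pathway;
#' lines with fewer than three fields or no members are rejected with their
#' line number.
#'
#' @param path GMT file path.
#' @return \code{readGmt}: named list of member-id character vectors, with
#'   descriptions in attribute \code{"description"}.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3)
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", i))
    out[[f[1]]] <- unique(f[-(1:2)])
    desc[f[1]] <- f[2]
  }
  if (anyDuplicated(names(out))) stop("duplicate pathway id in GMT")
  structure(out, description = desc)
}

#' @rdname readGmt
#' @param annotation named list of member-id vectors.
#' @param description optional named character vector of descriptions.
#' @export
writeGmt <- function(annotation, path, description = NULL) {
  lines <- vapply(names(annotation), function(id) {
    d <- if (!is.null(description) && !is.na(description[id]))
      description[[id]] else id
    paste(c(id, d, annotation[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column homolog id-mapping table
#'
#' @param path TSV with columns \code{source} and \code{target}; many-to-one
#'   and one-to-many mappings are permitted, empty ids are rejected.
#' @return data.frame(source, target).
#' @export
readIdMap <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target") %in% colnames(m)))
  if (any(is.na(m$source) | !nzchar(m$source) |
          is.na(m$target) | !nzchar(m$target)))
    stop("idmap contains empty ids")
  m[, c("source", "target")]
}

#' Read/write ROI rectangle tables
#'
#' ROI TSV columns: image_id, x0, y0, width, height (0-based, half-open).
#'
#' @param path TSV path.
#' @return \code{readRoiSet}: data.frame(image_id, x0, y0, width, height).
#' @export
readRoiSet <- function(path) {
  r <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("image_id", "x0", "y0", "width", "height") %in% colnames(r)))
  r
}

#' @rdname readRoiSet
#' @param rois data.frame to write.
#' @export
writeRoiSet <- function(rois, path) {
  utils::write.table(rois, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an assay-plate TSV
#'
#' Columns: well, role (standard|unknown), sample_id, known_amount,
#' response, time_min, protein_mg.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readPlate <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("well", "role", "response") %in% colnames(p)))
  if (!all(p$role %in% c("standard", "unknown")))
    stop("role must be 'standard' or 'unknown'")
  p
}

#' Write/read a 16-bit grayscale TIFF image
#'
#' @param image an [EMImage] (written) or file path (read).
#' @param path output TIFF path.
#' @return \code{readImageTiff}: an [EMImage].
#' @export
writeImageTiff <- function(image, path) {
  stopifnot(is(image, "EMImage"))
  tiff::writeTIFF(image@pixels, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeImageTiff
#' @param nmPerPx calibration to attach on read.
#' @param imageId identifier to attach on read.
#' @export
readImageTiff <- function(path, nmPerPx = 1, imageId = basename(path)) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  EMImage(px, nmPerPx = nmPerPx, imageId = imageId)
}

#' Write/read ground-truth JSON
#'
#' @param truth a ground-truth list from the simulators.
#' @param path JSON path.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# Polynomial rolling hash of a serialized object; stable fingerprint for
# manifests (kept below 2^31 so all arithmetic stays exact in doubles).
.configHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 3L))
  h <- 17
  for (b in bytes) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the synthetic-to-results pipeline
#'
#' Executes the selected stages in dependency order — \code{simulate} (the
#' synthetic study), \code{diff} (per-fraction permutation-FDR volcano),
#' \code{enrich} (integrated rank-enrichment MANOVA); \code{glycogen} and
#' \code{assay} run independently on simulated inputs. All randomness flows
#' from the global seed through [deriveSeed()], so re-running an identical
#' configuration reproduces byte-identical outputs. A JSON manifest with the
#' package version, seed, configuration hash, per-stage row counts and all
#' warnings is written alongside the result tables.
#'
#' @param seed global integer seed.
#' @param outDir output directory (created if needed).
#' @param stages subset of \code{c("simulate", "diff", "enrich", "glycogen",
#'   "assay")}.
#' @param simConfig a [SimStudyConfig()] (its seed is overridden by the
#'   derived stage seed).
#' @param volcano list of volcano parameters (s0, n_permutations,
#'   fdr_target, max_missing).
#' @param nPathways,sizeRange pathway annotation parameters.
#' @return The manifest, invisibly.
#' @export
runPipeline <- function(seed = 1L, outDir = tempfile("run"),
                        stages = c("simulate", "diff", "enrich"),
                        simConfig = SimStudyConfig(),
                        volcano = list(s0 = 0.1, n_permutations = 250L,
                                       fdr_target = 0.05, max_missing = 2L),
                        nPathways = 100L, sizeRange = c(5, 30)) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  warningsLog <- character()
  manifest <- list(artifact = "atriomics",
                   version = as.character(utils::packageVersion("atriomics")),
                   seed = as.integer(seed),
                   config_hash = .configHash(list(simConfig, volcano,
                                                  nPathways, sizeRange,
                                                  stages)),
                   stages = list())
  capture <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warningsLog <<- c(warningsLog, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  study <- NULL
  if (any(c("simulate", "diff", "enrich") %in% stages)) {
    simConfig$seed <- deriveSeed(seed, "simulate")
    study <- capture(simulateStudy(simConfig, nPathways = nPathways,
                                   sizeRange = sizeRange))
    for (d in names(study$proteomics))
      writeOmicsMatrix(study$proteomics[[d]],
                       file.path(outDir, sprintf("matrix_%s.tsv", d)),
                       file.path(outDir, sprintf("design_%s.tsv", d)))
    if (!is.null(study$transcripts))
      writeOmicsMatrix(study$transcripts,
                       file.path(outDir, "matrix_RNA.tsv"),
                       file.path(outDir, "design_RNA.tsv"))
    writeGmt(study$annotation, file.path(outDir, "pathways.gmt"))
    writeGroundTruth(study$truth, file.path(outDir, "ground_truth.json"))
    manifest$stages$simulate <- list(
      n_features = simConfig$n_features,
      datasets = c(names(study$proteomics),
                   if (!is.null(study$transcripts)) "RNA"),
      n_pathways = length(study$annotation))
  }
  if ("diff" %in% stages) {
    diffCounts <- list()
    for (d in names(study$proteomics)) {
      om <- capture(filterMissing(study$proteomics[[d]],
                                  volcano$max_missing))
      om <- capture(normalizeMatrix(om, log2 = TRUE, zscore = FALSE))
      vr <- capture(permutationVolcano(om, s0 = volcano$s0,
                                       nPermutations = volcano$n_permutations,
                                       fdrTarget = volcano$fdr_target,
                                       seed = deriveSeed(seed,
                                                         paste0("diff:", d))))
      tab <- as.data.frame(resultsTable(vr))
      utils::write.table(tab, file.path(outDir, sprintf("diff_%s.tsv", d)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      diffCounts[[d]] <- list(features_in = nrow(study$proteomics[[d]]),
                              features_tested = nrow(tab),
                              significant = sum(tab$significant))
    }
    manifest$stages$diff <- diffCounts
  }
  if ("enrich" %in% stages) {
    er <- capture(enrichPathways(study$proteomics, study$transcripts,
                                 study$annotation))
    tab <- as.data.frame(resultsTable(er))
    tab$k <- apply(er@results$k, 1L, paste, collapse = ";")
    tab$score <- apply(er@results$score, 1L, function(s)
      paste(format(s, digits = 6), collapse = ";"))
    utils::write.table(tab, file.path(outDir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(er@skipped),
                       file.path(outDir, "enrichment_skipped.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$enrich <- list(tested = nrow(er@results),
                                   skipped = nrow(er@skipped),
                                   significant = sum(er@results$significant))
  }
  if ("glycogen" %in% stages) {
    spec <- GranuleImageSpec(seed = deriveSeed(seed, "glycogen"))
    sim <- capture(simulateEMImage(spec))
    rois <- generateRois(spec$width, spec$height,
                         avoid = sim$truth$organelle_boxes,
                         seed = deriveSeed(seed, "glycogen:rois"))
    counts <- capture(countGranulesInImage(sim$image, rois))
    utils::write.table(counts, file.path(outDir, "granule_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$glycogen <- list(rois = nrow(rois),
                                     total_count = sum(counts$count),
                                     planted = spec$n_granules)
  }
  if ("assay" %in% stages) {
    act <- stats::setNames(c(2.5, 3.0, 3.5, 5.0, 5.5, 6.0),
                           sprintf("%s_%d", rep(c("AF", "sham"), each = 3),
                                   1:3))
    plate <- capture(simulateAssayPlate(act, noiseSd = 5,
                                        seed = deriveSeed(seed, "assay")))
    got <- capture(assayActivities(plate))
    utils::write.table(got, file.path(outDir, "assay_activities.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$assay <- list(wells = nrow(plate),
                                  unknowns = nrow(got))
  }
  manifest$warnings <- warningsLog
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
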