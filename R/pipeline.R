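#' Run the full interactivity pipeline
#'
#' Orchestrates the stages on one chromosome: obtain a contact map (either
#' simulated or read from disk), mask all-zero bins, distance-normalize,
#' build the transition matrix, compute the stationary profile, call HIRs
#' and flanks and, when tracks are configured, normalize tracks, apply the
#' exclusion rules, assemble the enrichment matrix and classify HIRs.
#' With a simulated map the planted truth is written and compared; with a
#' classification, between-class contact distributions are extracted from
#' the observed/expected map.
#'
#' Every output is listed in `manifest.json` together with the fully
#' resolved configuration and an md5 checksum per file, so a run can be
#' audited and reproduced; reruns with the same configuration and seed are
#' byte-identical.
#'
#' @param config a named list or a path to a YAML file.  Recognized
#'   entries:
#'   \describe{
#'     \item{simulate}{list of [simulateMap()] arguments (set to enable
#'       simulation), e.g. `list(nBins = 500, beta = 5, seed = 1)`.}
#'     \item{map, format, chrom, binSize, nBins}{alternatively, a contact
#'       map file to read.}
#'     \item{norm}{`"oe_subtract"` (default) or `"oe_divide"`.}
#'     \item{method}{stationary method, default `"eig"`.}
#'     \item{pct, minBins}{HIR-calling parameters, default 90 and 5.}
#'     \item{flankOffset}{F2 offset in bp, default 1e5.}
#'     \item{tracks}{list of [simulateTracks()] arguments (archetypes as a
#'       matrix) to enable the enrichment/classification stages.}
#'     \item{k, nComponents}{classification parameters, default 6 and 6.}
#'     \item{classContacts}{list with `nRandom` and `seed` to enable the
#'       between-class contact stage.}
#'   }
#' @param outDir output directory, created if needed.
#' @return the manifest, invisibly (a list).
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  put <- function(file) {
    outputs <<- c(outputs, file)
    file.path(outDir, file)
  }

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- do.call(simulateMap, config$simulate)
    map <- sim$map
    truth <- sim$truth
    writeContactMap(map, put("map.coo"), format = "coo")
    writeRegionsBed(truth, put("truth.bed"))
  } else {
    if (is.null(config$map))
      stop("config must provide either 'simulate' or a 'map' file")
    if (!file.exists(config$map))
      stop("contact map file not found: ", config$map)
    map <- readContactMap(config$map,
                          format = if (is.null(config$format)) "coo"
                                   else config$format,
                          chrom = if (is.null(config$chrom)) "chr1"
                                  else config$chrom,
                          binSize = if (is.null(config$binSize)) 5000
                                    else config$binSize,
                          nBins = config$nBins)
  }
  map <- maskZeroRows(map)

  norm <- if (is.null(config$norm)) "oe_subtract" else config$norm
  nm <- normalizeMap(map, kind = norm)
  tm <- buildTransitionMatrix(nm)
  method <- if (is.null(config$method)) "eig" else config$method
  prof <- stationaryDistribution(tm, method = method)
  profileToBedGraph(prof, put("stationary.bedgraph"))

  pct <- if (is.null(config$pct)) 90 else config$pct
  minBins <- if (is.null(config$minBins)) 5 else config$minBins
  hirs <- callHIRs(prof, q = pct, minBins = minBins)
  writeRegionsBed(hirs, put("hirs.bed"))
  offset <- if (is.null(config$flankOffset)) 1e5 else config$flankOffset
  flanks <- if (length(hirs)) makeFlanks(hirs, offset = offset) else NULL
  if (!is.null(flanks))
    writeRegionsBed(flanks, put("flanks.bed"))

  if (!is.null(truth) && length(hirs)) {
    rec <- hubRecovery(hirs, truth)
    utils::write.table(
      data.frame(recall = rec$recall, precision = rec$precision,
                 binRecall = rec$binRecall),
      put("hub_recovery.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }

  classes <- NULL
  if (!is.null(config$tracks) && length(hirs)) {
    targs <- config$tracks
    if (!is.null(targs$archetypes) && !is.matrix(targs$archetypes))
      targs$archetypes <- do.call(rbind, targs$archetypes)
    targs$truth <- truth
    simT <- do.call(simulateTracks, targs)
    normed <- lapply(simT$tracks, normalizeTrack)
    excl <- excludeDatasets(normed, hirs)
    if (nrow(excl$dropped))
      utils::write.table(excl$dropped, put("dropped_tracks.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(excl$kept) >= 2) {
      X <- assembleMatrix(excl$kept, hirs)
      utils::write.table(round(X, 6), put("enrichment_matrix.tsv"),
                         sep = "\t", quote = FALSE)
      k <- if (is.null(config$k)) 6 else config$k
      nc <- if (is.null(config$nComponents)) 6 else config$nComponents
      cls <- classifyHIRs(X, nComponents = nc, k = k)
      classes <- cls$classes
      clbed <- hirs
      S4Vectors::mcols(clbed)$name <-
        paste0(S4Vectors::mcols(hirs)$name, "_class", classes)
      writeRegionsBed(clbed, put("hir_classes.bed"))
    }
  }

  if (!is.null(config$classContacts) && !is.null(classes)) {
    oe <- normalizeMap(map, kind = "oe_divide")
    cc <- config$classContacts
    res <- classContacts(oe, hirs, classes,
                         nRandom = if (is.null(cc$nRandom)) 10000
                                   else cc$nRandom,
                         seed = cc$seed)
    utils::write.table(res$summary, put("class_contacts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    tool = "hirscan",
    version = as.character(utils::packageVersion("hirscan")),
    config = config,
    outputs = lapply(stats::setNames(outputs, outputs), function(f)
      list(md5 = unname(tools::md5sum(file.path(outDir, f)))))
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
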