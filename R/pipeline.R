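#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. Defaults are the
#' parameters of the published workflow: 7-40 residue detectable peptides,
#' at least two unique peptides, the both-replicate rule, FDR 0.05 with an
#' |log2FC| >= 1 gate, a two-fold trajectory filter, average-linkage
#' clustering under correlation distance cut at node depth 3 with clusters
#' over 500 proteins subset at node depth 5.
#'
#' @param simulate a [simulationConfig()] to generate the input, or `NULL`
#'   to read files.
#' @param intensityPath,metadataPath input files (used when `simulate` is
#'   `NULL`).
#' @param outputDir directory for all artifacts (created if absent).
#' @param minUniquePeptides,fdr,lfcGate,foldChangeFilter filter thresholds.
#' @param pairs comparison scheme for [depCountMatrix()].
#' @param clusterDepth,subsetThreshold,subsetDepth,distance,linkage
#'   clustering parameters.
#' @param pathwayModel a [PathwayModel] or path to one (JSON), or `NULL`
#'   to skip the pathway stage.
#' @param complexes a [ComplexCatalog] or GMT/TSV path, or `NULL` to skip
#'   the co-regulation stage.
#' @param localization a [LocalizationMap] or TSV path, or `NULL`.
#' @param annotations named term list or GMT path for cluster enrichment,
#'   or `NULL`.
#' @param seed integer seed for the simulated branch.
#' @return A validated config list of class `fermprotConfig`.
#' @export
pipelineConfig <- function(simulate = simulationConfig(),
                           intensityPath = NULL, metadataPath = NULL,
                           outputDir = tempfile("fermprot_run_"),
                           minUniquePeptides = 2, fdr = 0.05, lfcGate = 1,
                           foldChangeFilter = 1, pairs = "all",
                           clusterDepth = 3, subsetThreshold = 500,
                           subsetDepth = 5, distance = "pearson",
                           linkage = "average", pathwayModel = NULL,
                           complexes = NULL, localization = NULL,
                           annotations = NULL, seed = 1L) {
  if (is.null(simulate))
    stopIfNot(!is.null(intensityPath) && !is.null(metadataPath),
              "without a simulate block, intensityPath and metadataPath are required")
  cfg <- list(simulate = simulate, intensityPath = intensityPath,
              metadataPath = metadataPath, outputDir = outputDir,
              minUniquePeptides = minUniquePeptides, fdr = fdr,
              lfcGate = lfcGate, foldChangeFilter = foldChangeFilter,
              pairs = pairs, clusterDepth = clusterDepth,
              subsetThreshold = subsetThreshold, subsetDepth = subsetDepth,
              distance = distance, linkage = linkage,
              pathwayModel = pathwayModel, complexes = complexes,
              localization = localization, annotations = annotations,
              seed = as.integer(seed))
  class(cfg) <- "fermprotConfig"
  cfg
}

pipelineLog <- function(...) message("[fermprot] ", ...)

resolveInput <- function(x, reader) {
  if (is.null(x) || !is.character(x)) x else reader(x)
}

#' Run the full analysis pipeline
#'
#' Executes quantification, QC, differential expression, trajectory
#' clustering (with optional enrichment), pathway perturbation scoring and
#' co-regulation analysis in order, writing every intermediate table to the
#' output directory together with a machine-readable run manifest
#' (parameters, seed, per-stage row counts, and an MD5 checksum per output
#' file). Two runs with the same config produce byte-identical outputs.
#' Stages without the required annotation input are skipped with an
#' explicit manifest entry.
#'
#' @param config a [pipelineConfig()].
#' @return Invisibly, a list with the in-memory results (`experiment`,
#'   `truth`, `summed`, `normalized`, `replicateQC`, `depCounts`,
#'   `clusters`, `enrichment`, `pathwayRanking`, `coregulation`,
#'   `manifest`).
#' @export
runPipeline <- function(config) {
  stopIfNot(inherits(config, "fermprotConfig"),
            "config must come from pipelineConfig()")
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outputDir, f)
  manifest <- list(package = "fermprot",
                   version = as.character(utils::packageVersion("fermprot")),
                   seed = config$seed,
                   parameters = config[c("minUniquePeptides", "fdr",
                                         "lfcGate", "foldChangeFilter",
                                         "pairs", "clusterDepth",
                                         "subsetThreshold", "subsetDepth",
                                         "distance", "linkage")],
                   stages = list())
  truth <- NULL

  # --- input: simulate or read --------------------------------------------
  if (!is.null(config$simulate)) {
    pipelineLog("stage simulate")
    sim <- simulateTimecourse(config$simulate)
    se <- sim$experiment
    truth <- sim$truth
    writeIntensityTable(se, out("intensity_raw.tsv"))
    writeSampleMetadata(se, out("sample_metadata.tsv"))
    write_json(list(trajectoryClass = as.list(truth$trajectoryClass),
                    batchShift = truth$batchShift,
                    complexes = truth$complexes),
               out("ground_truth.json"), auto_unbox = TRUE, digits = NA)
    manifest$stages$simulate <- list(status = "run", nProteins = nrow(se),
                                     nSamples = ncol(se))
  } else {
    pipelineLog("stage read")
    se <- loadExperiment(config$intensityPath, config$metadataPath)
    manifest$stages$simulate <- list(status = "skipped")
  }

  # --- quantify / normalize -----------------------------------------------
  pipelineLog("stage quantify")
  filtered <- suppressWarnings(
    detectionFilter(se, minUniquePeptides = config$minUniquePeptides))
  centered <- log2MedianCenter(filtered)
  summed <- sumReplicates(filtered)
  normalized <- suppressWarnings(rowMeanNormalize(summed))
  writeIntensityTable(centered, out("log2_centered.tsv"))
  writeIntensityTable(summed, out("replicate_summed.tsv"))
  writeIntensityTable(normalized, out("row_mean_normalized.tsv"))
  manifest$stages$quantify <- list(status = "run",
                                   nProteinsAfterFilter = nrow(filtered))

  # --- qc ------------------------------------------------------------------
  pipelineLog("stage qc")
  qc <- replicateQC(se)  # on unmasked detections: discordance is the point
  sc <- suppressWarnings(sampleCorrelation(log2MedianCenter(filtered)))
  write.table(qc, out("replicate_qc.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample = rownames(corValues(sc)),
                         corValues(sc), check.names = FALSE),
              out("sample_correlation.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest$stages$qc <- list(status = "run", nTimePoints = nrow(qc),
                             meanReplicateR = mean(qc$r, na.rm = TRUE))

  # --- diffexp -------------------------------------------------------------
  pipelineLog("stage diffexp")
  de <- depCountMatrix(centered, pairs = config$pairs, fdr = config$fdr,
                       lfcGate = config$lfcGate)
  write.table(data.frame(timePoint = rownames(de$counts), de$counts,
                         check.names = FALSE),
              out("dep_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  deps <- do.call(rbind, lapply(names(de$tables), function(nm) {
    t <- de$tables[[nm]]
    t <- t[t$dep, , drop = FALSE]
    if (nrow(t)) cbind(comparison = nm, t) else NULL
  }))
  if (is.null(deps)) deps <- data.frame(comparison = character(0))
  write.table(deps, out("dep_table.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest$stages$diffexp <- list(status = "run",
                                  nComparisons = length(de$tables),
                                  maxDeps = max(de$counts))

  # --- cluster -------------------------------------------------------------
  pipelineLog("stage cluster")
  changed <- twofoldFilter(normalized, threshold = config$foldChangeFilter)
  clusters <- NULL
  enrichment <- NULL
  if (nrow(changed) >= 2) {
    tree <- suppressWarnings(
      hclusterProteins(changed, distance = config$distance,
                       linkage = config$linkage))
    clusters <- cutByNodeDepth(tree, depth = config$clusterDepth,
                               subsetThreshold = config$subsetThreshold,
                               subsetDepth = config$subsetDepth)
    write.table(clusters, out("cluster_assignments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeNewick(tree, out("dendrogram.nwk"))
    anns <- resolveInput(config$annotations, readGmt)
    if (!is.null(anns)) {
      universe <- rownames(se)
      enrichment <- do.call(rbind, lapply(split(clusters$protein,
                                                clusters$cluster),
        function(members) {
          e <- enrichTerms(members, anns, universe, fdr = config$fdr)
          cbind(cluster = clusters$cluster[match(members[1],
                                                 clusters$protein)], e)
        }))
      rownames(enrichment) <- NULL
      write.table(enrichment, out("cluster_enrichment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    manifest$stages$cluster <- list(status = "run",
                                    nChanged = nrow(changed),
                                    nClusters = length(unique(clusters$cluster)),
                                    enrichment = if (is.null(anns)) "skipped"
                                                 else "run")
  } else {
    manifest$stages$cluster <- list(status = "skipped",
                                    reason = "fewer than 2 changed proteins")
  }

  # --- pathway -------------------------------------------------------------
  model <- resolveInput(config$pathwayModel, readPathwayModel)
  ranking <- NULL
  if (!is.null(model)) {
    pipelineLog("stage pathway")
    ranking <- rankPathways(model, normalized)
    write.table(ranking, out("pathway_ranking.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$stages$pathway <- list(status = "run",
                                    nPathways = nrow(ranking))
  } else manifest$stages$pathway <- list(status = "skipped",
                                         reason = "no pathway model")

  # --- coregulation --------------------------------------------------------
  catalog <- resolveInput(config$complexes, readComplexCatalog)
  coreg <- NULL
  if (!is.null(catalog)) {
    pipelineLog("stage coregulation")
    pc <- suppressWarnings(proteinCorrelation(log2MedianCenter(summed)))
    coverage <- complexCoverage(catalog, rownames(summed))
    pcSplit <- pairCorrelationSplit(pc, catalog)
    write.table(coverage$perComplex, out("complex_coverage.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    groupSummary <- data.frame(
      group = c("interacting", "nonInteracting"),
      n = c(length(pcSplit$interacting), length(pcSplit$nonInteracting)),
      median = c(pcSplit$stats$medianInteracting,
                 pcSplit$stats$medianNonInteracting),
      mean = c(pcSplit$stats$meanInteracting,
               pcSplit$stats$meanNonInteracting))
    write.table(groupSummary, out("pair_correlation_groups.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    coreg <- list(coverage = coverage, split = pcSplit)
    locmap <- resolveInput(config$localization, readLocalizationMap)
    if (!is.null(locmap)) {
      comp <- suppressWarnings(compartmentCorrelation(pc, locmap))
      write.table(comp$summary, out("compartment_correlation.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      coreg$compartments <- comp
    }
    manifest$stages$coregulation <- list(status = "run",
                                         nComplexes =
                                           nrow(coverage$perComplex))
  } else manifest$stages$coregulation <- list(status = "skipped",
                                              reason = "no complex catalog")

  # --- manifest ------------------------------------------------------------
  files <- sort(setdiff(list.files(config$outputDir),
                        "run_manifest.json"))
  sums <- tools::md5sum(file.path(config$outputDir, files))
  manifest$outputs <- as.list(setNames(unname(sums), files))
  write_json(manifest, out("run_manifest.json"), auto_unbox = TRUE,
             pretty = TRUE, digits = NA)
  pipelineLog("done: ", length(files), " artifact(s) in ", config$outputDir)
  invisible(list(experiment = se, truth = truth, summed = summed,
                 normalized = normalized, replicateQC = qc,
                 depCounts = de$counts, clusters = clusters,
                 enrichment = enrichment, pathwayRanking = ranking,
                 coregulation = coreg, manifest = manifest))
}
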