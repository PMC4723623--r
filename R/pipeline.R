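#' Default run configuration
#'
#' All pipeline knobs in one list, each defaulting to the value the
#' analysis uses throughout: `rMin = 0.75` for edge calls, `B = 1000`
#' shuffles for the correlation null, `BRewire = 1000` rewiring
#' replicates, and `alpha = 0.05` on adjusted p-values for every test.
#'
#' @param out output directory.
#' @param seed master seed; per-group child seeds are derived with
#'   [groupSeed()].
#' @param input optional dataset directory to analyze; when `NULL` a
#'   synthetic dataset is simulated from `design`.
#' @param design an [experimentDesign()] (used when `input` is `NULL`).
#' @param ... overrides for any knob: `alpha`, `rMin`, `networkAlpha`,
#'   `minAbsLog2fc`, `anovaGate`, `B`, `BRewire`, `scheme`, `pooled`,
#'   `rewire`, `clusteringOver`, `trendSpec`, `networkSpecs`, `noiseSd`,
#'   `missingRate`, `randomizeWithinCultivarOnly`.
#' @return list of class `"RunConfig"`.
#' @export
runConfig <- function(out, seed = 1L, input = NULL,
                      design = experimentDesign(seed = seed), ...) {
  cfg <- list(
    out = out, seed = as.integer(seed), input = input, design = design,
    alpha = 0.05, networkAlpha = 0.05, rMin = 0.75,
    minAbsLog2fc = 1, anovaGate = 0.05,
    B = 1000L, BRewire = 1000L,
    scheme = "global", pooled = TRUE, rewire = "both",
    clusteringOver = "connected",
    trendSpec = defaultTrendSpec(), networkSpecs = NULL,
    noiseSd = 1, missingRate = 0,
    randomizeWithinCultivarOnly = TRUE)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config knob(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "RunConfig")
}

#' Load a run configuration from a YAML file
#'
#' The YAML keys mirror [runConfig()]; `design` sub-keys mirror
#' [experimentDesign()].
#'
#' @param path YAML file.
#' @return list of class `"RunConfig"`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$out)) stop("config must set 'out'")
  seed <- y$seed %||% 1L
  dy <- y$design %||% list()
  cc <- if (!is.null(dy$classCounts)) unlist(dy$classCounts) else
    defaultClassCounts()
  design <- experimentDesign(
    cultivars = dy$cultivars %||% c("CS", "ME"),
    stages = dy$stages %||% berryStages(),
    replicates = dy$replicates %||% 10L,
    years = dy$years %||% 2L,
    classCounts = cc, seed = seed)
  extra <- y[setdiff(names(y), c("out", "seed", "input", "design"))]
  if (!is.null(extra$trendSpec)) extra$trendSpec <- unlist(extra$trendSpec)
  do.call(runConfig, c(list(out = y$out, seed = seed,
                            input = y$input, design = design), extra))
}

#' Run the complete analysis pipeline
#'
#' Orchestrates simulate (or load) -> preprocess -> stage statistics ->
#' per-group correlation networks -> topology -> pairwise comparisons,
#' writing every artifact under `config$out` and a machine-readable
#' `report.json` (config echo, per-file checksums, per-group seeds). The
#' run is fully reproducible: identical config and seed give
#' byte-identical outputs.
#'
#' @param config a `"RunConfig"` from [runConfig()] /
#'   [readRunConfig()], or the path to a YAML config.
#' @return the report, invisibly (list mirroring `report.json`).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  out <- config$out
  dirs <- file.path(out, c("data", "stats", "networks", "topology",
                           "comparisons"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  steps <- list()
  stepStatus <- function(name) steps[[length(steps) + 1L]] <<- name

  ## -- data ---------------------------------------------------------------
  ds <- if (is.null(config$input)) {
    generateExperiment(config$design, trendSpec = config$trendSpec,
                       networkSpecs = config$networkSpecs,
                       noiseSd = config$noiseSd,
                       missingRate = config$missingRate)
  } else {
    readDataset(config$input, stageOrder = config$design$stages)
  }
  writeDataset(ds, file.path(out, "data"))
  me <- ds$experiment
  stepStatus("data")

  ## -- preprocessing ------------------------------------------------------
  lg <- log2Transform(medianNormalize(me))
  nx <- intensityMatrix(lg)
  write.table(data.frame(sample_id = rownames(nx), nx,
                         check.names = FALSE),
              file.path(out, "stats", "normalized_log2.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  med <- stageMedians(lg)
  stepStatus("preprocess")

  ## -- stage statistics ---------------------------------------------------
  cd <- SummarizedExperiment::colData(lg)
  cultivars <- unique(cd$cultivar)
  stages <- intersect(stageOrder(lg), unique(cd$stage))
  allTests <- list(); allCounts <- list()
  for (cv in cultivars) {
    tests <- stageTests(lg, cv, gate = config$anovaGate)
    allTests[[cv]] <- tests
    for (mode in c("vs_first", "vs_previous")) {
      allCounts[[paste(cv, mode)]] <-
        significantChanges(tests, mode, alpha = config$alpha,
                           stages = stages)
    }
    pca <- runPCA(lg, cultivar = cv)
    write.table(data.frame(sample_id = rownames(pca$scores), pca$scores),
                file.path(out, "stats", paste0("pca_scores_", cv, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(metabolite = rownames(pca$loadings),
                           pca$loadings),
                file.path(out, "stats", paste0("pca_loadings_", cv, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(do.call(rbind, allTests),
              file.path(out, "stats", "stage_tests.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(do.call(rbind, allCounts),
              file.path(out, "stats", "change_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(cultivars) == 2) {
    disc <- do.call(rbind, lapply(stages, function(st) {
      d <- cultivarDiscriminators(lg, st, alpha = config$alpha,
                                  minAbsLog2fc = config$minAbsLog2fc)
      if (nrow(d)) cbind(stage = st, d) else NULL
    }))
    if (is.null(disc)) {
      disc <- data.frame(stage = character(), metabolite = character(),
                         log2fc = numeric(), direction = numeric(),
                         p = numeric(), p_adj = numeric())
    }
    write.table(disc, file.path(out, "stats", "cultivar_discriminators.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeNewick(hcaTree(med), file.path(out, "stats", "hca.newick"))
  stepStatus("stats")

  ## -- correlation networks ------------------------------------------------
  networks <- list(); seeds <- list()
  ann <- metaboliteAnnotation(lg)
  for (cv in cultivars) for (st in stages) {
    key <- paste(cv, st, sep = ".")
    gseed <- groupSeed(config$seed, cv, st, "network")
    seeds[[key]] <- gseed
    x <- groupMatrix(lg, cv, st, minSamples = 4L)
    corr <- correlationGroup(x, group = c(cv, st), B = config$B,
                             seed = gseed, scheme = config$scheme,
                             pooled = config$pooled)
    net <- buildNetwork(corr, rMin = config$rMin,
                        alpha = config$networkAlpha)
    networks[[key]] <- net
    writeEdgeList(net, file.path(out, "networks",
                                 sprintf("edges_%s_%s.tsv", cv, st)))
    writeGraphML(net, file.path(out, "networks",
                                sprintf("network_%s_%s.graphml", cv, st)),
                 annotation = ann)
  }
  stepStatus("networks")

  ## -- topology ------------------------------------------------------------
  topo <- do.call(rbind, lapply(networks, function(n) {
    summarizeTopology(n, clusteringOver = config$clusteringOver)
  }))
  rownames(topo) <- NULL
  write.table(topo, file.path(out, "topology", "topology_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (key in names(networks)) {
    write.table(centralityTable(networks[[key]]),
                file.path(out, "topology",
                          paste0("centrality_", key, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    fit <- fitDegreeDistribution(networks[[key]])
    jsonlite::write_json(
      list(fitable = fit$fitable, selected = fit$selected,
           k = fit$k, ccdf = fit$ccdf,
           akaike_weights = as.list(fit$akaike_weights),
           fits = lapply(fit$fits, function(f) {
             f[c("params", "rss", "aic", "converged")]
           })),
      file.path(out, "topology", paste0("degree_fit_", key, ".json")),
      auto_unbox = TRUE, digits = NA, null = "null")
  }
  stepStatus("topology")

  ## -- comparisons ---------------------------------------------------------
  keys <- names(networks)
  pairRows <- list()
  for (i in seq_along(keys)) for (j in seq_along(keys)) {
    if (j <= i) next
    a <- networks[[keys[i]]]; b <- networks[[keys[j]]]
    sameCultivar <- a@group[1] == b@group[1]
    doRewire <- config$BRewire >= 100 &&
      nrow(a@edges) >= 2 && nrow(b@edges) >= 2 &&
      (sameCultivar || !config$randomizeWithinCultivarOnly)
    cmpSeed <- groupSeed(config$seed, keys[i], keys[j], "compare")
    cmp <- if (doRewire) {
      ov <- randomizationTest(a, b, "overlap", B = config$BRewire,
                              seed = cmpSeed, rewire = config$rewire)
      pd <- randomizationTest(a, b, "avg_path_difference",
                              B = config$BRewire, seed = cmpSeed,
                              rewire = config$rewire)
      ov@pathDifference <- pd@pathDifference
      ov@rewirePathP <- pd@rewirePathP
      ov
    } else {
      edgeOverlap(a, b)
    }
    pairRows[[paste(keys[i], keys[j])]] <- data.frame(
      network_a = keys[i], network_b = keys[j],
      shared = cmp@shared, only_a = cmp@onlyA, only_b = cmp@onlyB,
      overlap_pct_a = cmp@overlapPctA, overlap_pct_b = cmp@overlapPctB,
      fisher_p = cmp@fisherP,
      rewire_overlap_p = cmp@rewireOverlapP,
      avg_path_difference = cmp@pathDifference,
      rewire_path_p = cmp@rewirePathP,
      stringsAsFactors = FALSE)
  }
  overlapTab <- do.call(rbind, pairRows)
  rownames(overlapTab) <- NULL
  write.table(overlapTab, file.path(out, "comparisons",
                                    "overlap_matrix.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stepStatus("compare")

  ## -- report --------------------------------------------------------------
  files <- sort(setdiff(list.files(out, recursive = TRUE),
                        "report.json"))
  checksums <- as.list(unname(md5sum(file.path(out, files))))
  names(checksums) <- files
  report <- list(
    package_version = as.character(utils::packageVersion("berrynet")),
    seed = config$seed,
    config = config[setdiff(names(config), c("design", "networkSpecs"))],
    design = config$design[c("cultivars", "stages", "replicates", "years",
                             "nMetabolites")],
    group_seeds = seeds,
    steps_completed = unlist(steps),
    files = checksums)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(report)
}
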