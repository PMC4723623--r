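#' Write a synthetic dataset to a directory of TSV files
#'
#' Emits `intensities.tsv` (rows = samples, columns = metabolite ids,
#' missing entries as empty fields), `samples.tsv`, `metabolites.tsv` and
#' `planted_edges.tsv`. Numeric values are written with full double
#' precision so that a write/read round trip is an identity.
#'
#' @param dataset a `"SyntheticDataset"` from [generateExperiment()], or a
#'   bare \linkS4class{MetaboliteExperiment} (no planted edges written).
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  if (inherits(dataset, "SyntheticDataset")) {
    me <- dataset$experiment
    planted <- dataset$planted
  } else if (is(dataset, "MetaboliteExperiment")) {
    me <- dataset
    planted <- list()
  } else {
    stop("dataset must be a SyntheticDataset or MetaboliteExperiment")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  x <- intensityMatrix(me)
  df <- data.frame(sample_id = rownames(x),
                   apply(x, 2, function(v) {
                     ifelse(is.na(v), "", sprintf("%.17g", v))
                   }),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, file.path(dir, "intensities.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sampleAnnotation(me), file.path(dir, "samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(metaboliteAnnotation(me), file.path(dir, "metabolites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ed <- do.call(rbind, lapply(planted, function(pn) {
    if (!nrow(pn$edges)) return(NULL)
    data.frame(cultivar = pn$group[1], stage = pn$group[2],
               node_a = pn$edges$from, node_b = pn$edges$to,
               sign = pn$edges$sign, target_r = pn$edges$target_r,
               stringsAsFactors = FALSE)
  }))
  if (is.null(ed)) {
    ed <- data.frame(cultivar = character(), stage = character(),
                     node_a = character(), node_b = character(),
                     sign = numeric(), target_r = numeric())
  }
  write.table(ed, file.path(dir, "planted_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a dataset directory written by [writeDataset()]
#'
#' @param dir directory containing `intensities.tsv`, `samples.tsv`,
#'   `metabolites.tsv` and (optionally) `planted_edges.tsv`.
#' @param stageOrder ordered stage labels. When supplied, samples carrying
#'   a stage outside this list are rejected before any computation; the
#'   default (`NULL`) accepts the six berry stages plus any extra labels
#'   found in `samples.tsv`, in order of appearance.
#' @return A `"SyntheticDataset"` list with `experiment` and `planted`.
#' @export
readDataset <- function(dir, stageOrder = NULL) {
  readTsv <- function(name, required) {
    path <- file.path(dir, name)
    if (!file.exists(path)) stop("missing file: ", path)
    df <- tryCatch(
      read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                 na.strings = ""),
      error = function(e) stop("cannot parse ", name, ": ",
                               conditionMessage(e))
    )
    miss <- setdiff(required, colnames(df))
    if (length(miss)) {
      stop(name, " is missing column(s): ", paste(miss, collapse = ", "))
    }
    df
  }
  ints <- readTsv("intensities.tsv", "sample_id")
  if (ncol(ints) < 2 || nrow(ints) == 0) {
    stop("intensities.tsv contains no metabolite data")
  }
  samples <- readTsv("samples.tsv", c("sample_id", "cultivar", "stage", "year"))
  metabolites <- readTsv("metabolites.tsv",
                         c("metabolite_id", "name", "class"))
  x <- as.matrix(ints[, -1, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- as.character(ints$sample_id)
  stages <- stageOrder %||% unique(c(berryStages(), samples$stage))
  bad <- setdiff(unique(samples$stage), stages)
  if (length(bad)) {
    stop("samples.tsv contains unknown stage label(s): ",
         paste(bad, collapse = ", "))
  }
  me <- MetaboliteExperiment(x, samples, metabolites, stageOrder = stages)

  planted <- list()
  epath <- file.path(dir, "planted_edges.tsv")
  if (file.exists(epath)) {
    ed <- readTsv("planted_edges.tsv",
                  c("cultivar", "stage", "node_a", "node_b", "sign",
                    "target_r"))
    if (nrow(ed)) {
      for (key in unique(paste(ed$cultivar, ed$stage, sep = "."))) {
        sub <- ed[paste(ed$cultivar, ed$stage, sep = ".") == key, ]
        planted[[key]] <- structure(
          list(group = c(sub$cultivar[1], sub$stage[1]),
               nodes = metabolites$metabolite_id,
               edges = data.frame(from = sub$node_a, to = sub$node_b,
                                  sign = sub$sign,
                                  target_r = sub$target_r,
                                  stringsAsFactors = FALSE),
               model = "unknown", params = list()),
          class = "PlantedNetwork")
      }
    }
  }
  structure(list(experiment = me, planted = planted,
                 trendSpec = NULL, design = NULL),
            class = "SyntheticDataset")
}

#' Write a network's edge list to TSV
#' @param network a \linkS4class{MetaboliteNetwork}.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(network, path) {
  write.table(networkEdges(network), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Export a network as GraphML with node and edge attributes
#'
#' Node attributes: `name`, `class` (when annotation is supplied) and
#' `degree`; edge attributes: `r` and `sign`.
#'
#' @param network a \linkS4class{MetaboliteNetwork}.
#' @param path output `.graphml` file.
#' @param annotation optional metabolite annotation data.frame
#'   (`metabolite_id`, `name`, `class`).
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(network, path, annotation = NULL) {
  g <- asIgraph(network)
  igraph::V(g)$degree <- igraph::degree(g)
  if (!is.null(annotation)) {
    idx <- match(igraph::V(g)$name, annotation$metabolite_id)
    igraph::V(g)$label <- annotation$name[idx]
    igraph::V(g)$class <- annotation$class[idx]
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
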