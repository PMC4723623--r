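#' Construct a MetaboliteExperiment from annotated tables
#'
#' Builds the package's central container from a samples-by-metabolites
#' intensity table plus sample and metabolite annotation tables. The
#' intensity table is stored transposed (metabolites as rows) following the
#' SummarizedExperiment convention of features in rows.
#'
#' @param intensities numeric matrix or data.frame, samples in rows and
#'   metabolites in columns; strictly positive where observed, `NA` allowed.
#' @param samples data.frame with one row per sample: `sample_id`,
#'   `cultivar`, `stage`, `year` (row order must match `intensities` rows).
#' @param metabolites data.frame with one row per metabolite:
#'   `metabolite_id`, `name`, `class`.
#' @param stageOrder character, ordered developmental stage labels; defaults
#'   to the six berry stages flowering through ripening.
#' @param processing processing tag of the supplied values
#'   (default `"raw"`).
#' @return A \linkS4class{MetaboliteExperiment}.
#' @examples
#' ds <- generateExperiment(experimentDesign(nMetabolites = 12,
#'   classCounts = c(sugar = 6, `amino acid` = 6), replicates = 4, seed = 1))
#' me <- ds$experiment
#' me
#' @export
MetaboliteExperiment <- function(intensities, samples, metabolites,
                                 stageOrder = berryStages(),
                                 processing = "raw") {
  needS <- c("sample_id", "cultivar", "stage", "year")
  missS <- setdiff(needS, colnames(samples))
  if (length(missS)) {
    stop("sample annotation is missing column(s): ", paste(missS, collapse = ", "))
  }
  needM <- c("metabolite_id", "name", "class")
  missM <- setdiff(needM, colnames(metabolites))
  if (length(missM)) {
    stop("metabolite annotation is missing column(s): ", paste(missM, collapse = ", "))
  }
  m <- as.matrix(intensities)
  if (!nrow(m) || !ncol(m)) stop("intensity table is empty")
  storage.mode(m) <- "double"
  if (is.null(rownames(m))) rownames(m) <- samples$sample_id
  if (is.null(colnames(m))) colnames(m) <- metabolites$metabolite_id
  if (!identical(rownames(m), as.character(samples$sample_id))) {
    stop("intensity row names do not match sample_id order")
  }
  if (!identical(colnames(m), as.character(metabolites$metabolite_id))) {
    stop("intensity column names do not match metabolite_id order")
  }
  cd <- S4Vectors::DataFrame(
    cultivar = as.character(samples$cultivar),
    stage = as.character(samples$stage),
    year = samples$year,
    row.names = as.character(samples$sample_id)
  )
  rd <- S4Vectors::DataFrame(
    name = as.character(metabolites$name),
    class = as.character(metabolites$class),
    row.names = as.character(metabolites$metabolite_id)
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = t(m)), colData = cd, rowData = rd
  )
  new("MetaboliteExperiment", se,
      processing = processing, stageOrder = stageOrder)
}

#' The six berry developmental stage labels, in order
#'
#' Flowering (FLW), fruit setting (FS), pre-veraison (PRV), veraison (VR),
#' post-veraison (PSV) and ripening (RP).
#' @return character(6)
#' @export
berryStages <- function() c("FLW", "FS", "PRV", "VR", "PSV", "RP")

#' @rdname berrynet-generics
#' @export
setMethod("processing", "MetaboliteExperiment", function(object) object@processing)

#' @rdname berrynet-generics
#' @export
setMethod("stageOrder", "MetaboliteExperiment", function(object) object@stageOrder)

#' @describeIn MetaboliteExperiment samples-by-metabolites intensity matrix;
#'   optionally restricted to one cultivar/stage group.
#' @param object,x a `MetaboliteExperiment`.
#' @param cultivar,stage optional labels to subset samples.
#' @export
setMethod("intensityMatrix", "MetaboliteExperiment",
  function(object, cultivar = NULL, stage = NULL) {
    keep <- rep(TRUE, ncol(object))
    cd <- SummarizedExperiment::colData(object)
    if (!is.null(cultivar)) keep <- keep & cd$cultivar %in% cultivar
    if (!is.null(stage)) keep <- keep & cd$stage %in% stage
    t(SummarizedExperiment::assay(object)[, keep, drop = FALSE])
  }
)

#' @rdname berrynet-generics
#' @export
setMethod("metaboliteAnnotation", "MetaboliteExperiment", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  data.frame(metabolite_id = rownames(object), name = rd$name,
             class = rd$class, row.names = NULL)
})

#' @rdname berrynet-generics
#' @export
setMethod("sampleAnnotation", "MetaboliteExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  data.frame(sample_id = colnames(object), cultivar = cd$cultivar,
             stage = cd$stage, year = cd$year, row.names = NULL)
})

setMethod("show", "MetaboliteExperiment", function(object) {
  cat("MetaboliteExperiment (", object@processing, ")\n", sep = "")
  cat("  ", nrow(object), " metabolites x ", ncol(object), " samples\n", sep = "")
  cd <- SummarizedExperiment::colData(object)
  cat("  cultivars:", paste(unique(cd$cultivar), collapse = ", "), "\n")
  cat("  stages:", paste(intersect(object@stageOrder, unique(cd$stage)),
                         collapse = " -> "), "\n")
  n_na <- sum(is.na(SummarizedExperiment::assay(object)))
  if (n_na) cat("  missing values:", n_na, "\n")
})

## Per-group samples-by-metabolites matrix with a guard on group size.
groupMatrix <- function(me, cultivar, stage, minSamples = 1L) {
  x <- intensityMatrix(me, cultivar = cultivar, stage = stage)
  if (nrow(x) < minSamples) {
    stop("group ", cultivar, "/", stage, " has ", nrow(x),
         " samples (need >= ", minSamples, ")")
  }
  x
}
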