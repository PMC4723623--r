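#' Median-normalize a raw intensity matrix
#'
#' Divides each metabolite's raw values by the median of all its
#' measurements over the whole experiment (both cultivars, all stages and
#' seasons), ignoring missing entries. After normalization every
#' metabolite's median equals 1. Even-length medians use the mean of the
#' two central order statistics.
#'
#' @param me a raw \linkS4class{MetaboliteExperiment}.
#' @return A `MetaboliteExperiment` tagged `"normalized"`.
#' @examples
#' ds <- generateExperiment(experimentDesign(nMetabolites = 8,
#'   classCounts = c(sugar = 8), replicates = 4, seed = 1))
#' nrm <- medianNormalize(ds$experiment)
#' processing(nrm)
#' @export
medianNormalize <- function(me) {
  stopifnot(is(me, "MetaboliteExperiment"))
  if (processing(me) != "raw") {
    stop("medianNormalize expects a raw matrix; this one is already '",
         processing(me), "'")
  }
  a <- SummarizedExperiment::assay(me)  # metabolites x samples
  med <- apply(a, 1, median, na.rm = TRUE)
  bad <- !is.finite(med)
  if (any(bad)) {
    stop("metabolite(s) with no observed values: ",
         paste(rownames(a)[bad], collapse = ", "))
  }
  SummarizedExperiment::assay(me) <- a / med
  me@processing <- "normalized"
  validObject(me)
  me
}

#' Log2-transform a normalized intensity matrix
#'
#' Elementwise log2; missing values stay missing. Values must be strictly
#' positive wherever observed.
#'
#' @param me a normalized \linkS4class{MetaboliteExperiment}.
#' @return A `MetaboliteExperiment` tagged `"log2"`.
#' @export
log2Transform <- function(me) {
  stopifnot(is(me, "MetaboliteExperiment"))
  if (processing(me) != "normalized") {
    stop("log2Transform expects a normalized matrix; this one is '",
         processing(me), "'")
  }
  a <- SummarizedExperiment::assay(me)
  bad <- which(!is.na(a) & a <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-positive value at metabolite ", rownames(a)[bad[1, 1]],
         ", sample ", colnames(a)[bad[1, 2]])
  }
  SummarizedExperiment::assay(me) <- log2(a)
  me@processing <- "log2"
  validObject(me)
  me
}

#' Per-group stage medians of log2 metabolite levels
#'
#' Median level of each metabolite across replicates for every
#' (cultivar, stage) group; the input to hierarchical clustering and the
#' fold-change proxy used throughout. Columns are ordered stage-within-
#' cultivar following the developmental stage order.
#'
#' @param me a log2 \linkS4class{MetaboliteExperiment}.
#' @return numeric matrix, metabolites by `<cultivar>.<stage>` groups.
#' @export
stageMedians <- function(me) {
  stopifnot(is(me, "MetaboliteExperiment"))
  if (processing(me) != "log2") {
    stop("stageMedians expects log2 data; this matrix is '",
         processing(me), "'")
  }
  cd <- SummarizedExperiment::colData(me)
  bad <- setdiff(unique(cd$stage), stageOrder(me))
  if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  a <- SummarizedExperiment::assay(me)
  groups <- expand.grid(stage = stageOrder(me),
                        cultivar = unique(cd$cultivar),
                        stringsAsFactors = FALSE)[, c("cultivar", "stage")]
  keep <- mapply(function(cv, st) any(cd$cultivar == cv & cd$stage == st),
                 groups$cultivar, groups$stage)
  groups <- groups[keep, , drop = FALSE]
  out <- vapply(seq_len(nrow(groups)), function(g) {
    cols <- cd$cultivar == groups$cultivar[g] & cd$stage == groups$stage[g]
    apply(a[, cols, drop = FALSE], 1, median, na.rm = TRUE)
  }, numeric(nrow(a)))
  out <- matrix(out, nrow = nrow(a),
                dimnames = list(rownames(a),
                                paste(groups$cultivar, groups$stage,
                                      sep = ".")))
  out
}
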