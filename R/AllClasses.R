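#' MetaboliteExperiment: annotated metabolite intensity matrix
#'
#' The pipeline's universal currency: a
#' \linkS4class{SummarizedExperiment} whose single assay holds metabolite
#' intensities (rows = metabolites, columns = samples), with sample
#' annotations (`cultivar`, `stage`, `year`) in `colData` and metabolite
#' annotations (`name`, `class`) in `rowData`. A processing tag records
#' where the object is in the fixed `raw -> normalized -> log2` chain, so
#' that transforms cannot be silently applied twice or out of order.
#'
#' @slot processing character, one of `"raw"`, `"normalized"`, `"log2"`.
#' @slot stageOrder character, the ordered developmental stage labels.
#'
#' @seealso [MetaboliteExperiment()] for construction,
#'   [medianNormalize()], [log2Transform()].
#' @export
setClass("MetaboliteExperiment",
  contains = "SummarizedExperiment",
  slots = c(processing = "character", stageOrder = "character")
)

setValidity("MetaboliteExperiment", function(object) {
  msg <- character()
  if (length(object@processing) != 1L ||
      !object@processing %in% c("raw", "normalized", "log2")) {
    msg <- c(msg, "processing tag must be one of 'raw', 'normalized', 'log2'")
  }
  cd <- SummarizedExperiment::colData(object)
  rd <- SummarizedExperiment::rowData(object)
  need_cd <- c("cultivar", "stage", "year")
  if (!all(need_cd %in% colnames(cd))) {
    msg <- c(msg, paste("colData must contain:", paste(need_cd, collapse = ", ")))
  }
  if (!all(c("name", "class") %in% colnames(rd))) {
    msg <- c(msg, "rowData must contain columns 'name' and 'class'")
  }
  if (anyDuplicated(object@stageOrder)) {
    msg <- c(msg, "stage order labels must be unique")
  }
  if ("stage" %in% colnames(cd) &&
      !all(cd$stage %in% object@stageOrder)) {
    msg <- c(msg, "every sample stage must appear in stageOrder")
  }
  a <- SummarizedExperiment::assay(object)
  if (object@processing %in% c("raw", "normalized") &&
      any(a[!is.na(a)] <= 0)) {
    msg <- c(msg, "raw/normalized intensities must be strictly positive")
  }
  if (is.null(rownames(object)) || is.null(colnames(object)) ||
      anyDuplicated(rownames(object)) || anyDuplicated(colnames(object))) {
    msg <- c(msg, "metabolite and sample ids must be present and unique")
  }
  if (length(msg)) msg else TRUE
})

#' CorrelationResult: per-group Spearman matrix with permutation p-values
#'
#' Symmetric Spearman correlation matrix for one (cultivar, stage) group,
#' together with the empirical p-value matrix obtained from the pooled
#' matrix-shuffle null and its Benjamini--Hochberg adjustment over the
#' `choose(m, 2)` off-diagonal family.
#'
#' @slot group character(2), cultivar and stage labels.
#' @slot r symmetric numeric matrix of Spearman coefficients, diagonal 1.
#' @slot pEmp symmetric matrix of empirical two-sided p-values.
#' @slot pAdj symmetric matrix of BH-adjusted p-values.
#' @slot nShuffles integer, number of matrix shuffles behind the null.
#' @slot nullSize integer, pooled null sample size.
#' @slot nSamples integer, samples in the group.
#' @export
setClass("CorrelationResult",
  slots = c(
    group = "character", r = "matrix", pEmp = "matrix", pAdj = "matrix",
    nShuffles = "integer", nullSize = "integer", nSamples = "integer"
  )
)

setValidity("CorrelationResult", function(object) {
  msg <- character()
  r <- object@r
  if (nrow(r) != ncol(r)) msg <- c(msg, "r must be square")
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-12, check.attributes = FALSE))) {
    msg <- c(msg, "r must be symmetric")
  }
  if (any(abs(r[!is.na(r)]) > 1 + 1e-12)) msg <- c(msg, "r must lie in [-1, 1]")
  if (!isTRUE(all.equal(unname(diag(r)), rep(1, nrow(r))))) {
    msg <- c(msg, "diag(r) must be 1")
  }
  p <- object@pEmp[!is.na(object@pEmp)]
  if (any(p <= 0 | p > 1)) msg <- c(msg, "empirical p-values must be in (0, 1]")
  off <- upper.tri(object@r)
  ok <- !is.na(object@pAdj[off]) & !is.na(object@pEmp[off])
  if (any(object@pAdj[off][ok] < object@pEmp[off][ok] - 1e-12)) {
    msg <- c(msg, "BH-adjusted p must be >= empirical p")
  }
  if (length(msg)) msg else TRUE
})

#' MetaboliteNetwork: signed correlation network over the metabolite universe
#'
#' Undirected graph whose nodes are the full metabolite universe (isolated
#' nodes retained) and whose edges are metabolite pairs passing both the
#' correlation threshold `|r| > rMin` and the FDR cut on the permutation
#' p-value. Each edge carries its Spearman coefficient and sign.
#'
#' @slot group character(2), cultivar and stage labels.
#' @slot nodes character vector, the metabolite universe.
#' @slot edges data.frame with columns `from`, `to`, `r`, `sign`,
#'   `p_emp`, `p_adj`.
#' @slot rMin numeric correlation threshold (edges require `|r| > rMin`).
#' @slot alpha numeric FDR level used for edge calls.
#' @export
setClass("MetaboliteNetwork",
  slots = c(
    group = "character", nodes = "character", edges = "data.frame",
    rMin = "numeric", alpha = "numeric"
  )
)

setValidity("MetaboliteNetwork", function(object) {
  msg <- character()
  e <- object@edges
  need <- c("from", "to", "r", "sign")
  if (!all(need %in% colnames(e))) {
    msg <- c(msg, paste("edges need columns:", paste(need, collapse = ", ")))
  } else if (nrow(e)) {
    if (!all(e$from %in% object@nodes) || !all(e$to %in% object@nodes)) {
      msg <- c(msg, "edge endpoints must belong to the node universe")
    }
    if (any(e$from == e$to)) msg <- c(msg, "self-edges are not allowed")
    key <- encodePairs(e$from, e$to, object@nodes)
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges are not allowed")
    if (any(abs(e$r) <= object@rMin)) {
      msg <- c(msg, "every edge must satisfy |r| > rMin")
    }
    if (!all(e$sign %in% c(-1, 1)) || any(sign(e$r) != e$sign)) {
      msg <- c(msg, "edge sign must be sign(r)")
    }
  }
  if (anyDuplicated(object@nodes)) msg <- c(msg, "node ids must be unique")
  if (length(msg)) msg else TRUE
})

#' ComparisonResult: edge overlap between two networks with significance
#'
#' Shared/unique edge counts for a pair of networks over an identical node
#' universe, the 2x2 Fisher table on the `choose(N, 2)` pair universe with
#' its one-sided p-value, and (when the randomization test has been run)
#' degree-preserving rewiring-null p-values for edge overlap and
#' average-path-length difference.
#'
#' @slot groupA,groupB character(2) group labels of the two networks.
#' @slot shared integer, edges present in both networks (unsigned pairs).
#' @slot onlyA,onlyB integer, edges unique to each network.
#' @slot universeSize integer, `choose(N, 2)` candidate pairs.
#' @slot overlapPctA,overlapPctB numeric, `shared / |E_ref| * 100` with each
#'   network as reference.
#' @slot fisherP numeric, one-sided (enrichment) Fisher p-value.
#' @slot rewireOverlapP,rewirePathP numeric, rewiring-null p-values
#'   (`NA` until [randomizationTest()] is run).
#' @slot pathDifference numeric, observed average-path-length difference.
#' @slot nRewires integer, rewiring replicates. @slot seed integer seed used.
#' @export
setClass("ComparisonResult",
  slots = c(
    groupA = "character", groupB = "character",
    shared = "integer", onlyA = "integer", onlyB = "integer",
    universeSize = "integer",
    overlapPctA = "numeric", overlapPctB = "numeric",
    fisherP = "numeric",
    rewireOverlapP = "numeric", rewirePathP = "numeric",
    pathDifference = "numeric", nRewires = "integer", seed = "integer"
  )
)

setValidity("ComparisonResult", function(object) {
  msg <- character()
  if (object@shared < 0 || object@onlyA < 0 || object@onlyB < 0) {
    msg <- c(msg, "edge counts must be non-negative")
  }
  tot <- object@shared + object@onlyA + object@onlyB
  if (tot > object@universeSize) {
    msg <- c(msg, "edge counts exceed the pair universe")
  }
  for (p in c(object@fisherP, object@rewireOverlapP, object@rewirePathP)) {
    if (!is.na(p) && (p <= 0 || p > 1)) msg <- c(msg, "p-values must be in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})
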