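#' Edge overlap between two networks
#'
#' Edges are compared as unordered, unsigned metabolite pairs over the two
#' networks' (identical) node universe. The overlap percent is reported
#' relative to each network as reference, `shared / |E_ref| * 100`, which
#' is why overlap is reference-asymmetric. The 2x2 Fisher table over the
#' `choose(N, 2)` candidate-pair universe is filled in; its test is run by
#' [fisherOverlapTest()].
#'
#' @param netA,netB \linkS4class{MetaboliteNetwork}s sharing a node
#'   universe.
#' @param signAware if `TRUE`, edges only match when their correlation
#'   signs agree (default `FALSE`: sign is ignored for overlap).
#' @return A \linkS4class{ComparisonResult} (counts and Fisher p filled;
#'   rewiring-null fields `NA` until [randomizationTest()]).
#' @export
edgeOverlap <- function(netA, netB, signAware = FALSE) {
  if (!identical(sort(netA@nodes), sort(netB@nodes))) {
    stop("networks must share an identical node universe")
  }
  universe <- netA@nodes
  keyA <- encodePairs(netA@edges$from, netA@edges$to, universe)
  keyB <- encodePairs(netB@edges$from, netB@edges$to, universe)
  if (signAware) {
    keyA <- keyA * 2 + (netA@edges$sign > 0)
    keyB <- keyB * 2 + (netB@edges$sign > 0)
  }
  shared <- length(intersect(keyA, keyB))
  nA <- length(keyA); nB <- length(keyB)
  M <- choose(length(universe), 2)
  pctA <- if (nA > 0) 100 * shared / nA else NA_real_
  pctB <- if (nB > 0) 100 * shared / nB else NA_real_
  cmp <- new("ComparisonResult",
             groupA = netA@group, groupB = netB@group,
             shared = as.integer(shared),
             onlyA = as.integer(nA - shared),
             onlyB = as.integer(nB - shared),
             universeSize = as.integer(M),
             overlapPctA = pctA, overlapPctB = pctB,
             fisherP = NA_real_,
             rewireOverlapP = NA_real_, rewirePathP = NA_real_,
             pathDifference = NA_real_, nRewires = 0L, seed = NA_integer_)
  cmp@fisherP <- fisherOverlapTest(cmp)
  cmp
}

#' One-sided Fisher test for edge-overlap enrichment
#'
#' Tests whether two networks share more edges than expected if each
#' placed its edges independently over the `choose(N, 2)` candidate
#' pairs: the one-sided (enrichment) hypergeometric tail of the 2x2 table
#' (shared, A-only, B-only, neither).
#'
#' @param comparison a \linkS4class{ComparisonResult} (or a network pair
#'   via [edgeOverlap()]).
#' @return p-value.
#' @export
fisherOverlapTest <- function(comparison) {
  stopifnot(is(comparison, "ComparisonResult"))
  s <- comparison@shared
  oa <- comparison@onlyA
  ob <- comparison@onlyB
  neither <- comparison@universeSize - s - oa - ob
  tab <- matrix(c(s, oa, ob, neither), 2, 2)
  fisher.test(tab, alternative = "greater")$p.value
}

#' Degree-preserving rewiring of a network
#'
#' Randomizes the wiring by repeated double-edge swaps, conserving every
#' node's degree exactly. Swaps that would create a self-edge or duplicate
#' edge are rejected (the attempt is consumed). Graphs admitting no valid
#' swap (e.g. a star or a single triangle) come back unchanged with
#' `rewired = FALSE` in the metadata.
#'
#' @param network a \linkS4class{MetaboliteNetwork} with >= 2 edges.
#' @param nAttempts swap attempts (default `10 * |E|`).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return the rewired \linkS4class{MetaboliteNetwork}; edge attributes
#'   (`r`, sign) follow the surviving edge slots. Attribute `rewired`
#'   (logical) and `swaps` (successful swap count) are attached.
#' @export
rewireNetwork <- function(network, nAttempts = NULL, seed = NULL) {
  e <- network@edges
  if (nrow(e) < 2) {
    stop("rewiring needs at least 2 edges")
  }
  if (is.null(nAttempts)) nAttempts <- 10L * nrow(e)
  idx <- cbind(match(e$from, network@nodes), match(e$to, network@nodes))
  run <- function() rewire_edges_cpp(idx, length(network@nodes),
                                     as.integer(nAttempts))
  res <- if (is.null(seed)) run() else withSeed(seed, run())
  out <- network
  out@edges$from <- network@nodes[res$edges[, 1]]
  out@edges$to <- network@nodes[res$edges[, 2]]
  attr(out@edges, "rewired") <- res$successes > 0
  attr(out@edges, "swaps") <- res$successes
  validObject(out)
  out
}

## Internal: average shortest-path length over connected pairs from an
## integer edge matrix (same convention as summarizeTopology).
avgPathFromEdges <- function(edgeIdx, nNodes) {
  g <- igraph::make_empty_graph(n = nNodes, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(edgeIdx)))
  igraph::mean_distance(g, unconnected = TRUE)
}

#' Rewiring randomization test for network overlap / path difference
#'
#' Estimates the chance level of an observed comparison statistic under
#' degree-preserving randomization. Per replicate the networks are
#' independently rewired (`rewire = "both"`, default) or only the first is
#' (`rewire = "one"`), and the statistic recomputed:
#' \describe{
#'   \item{overlap}{shared edge count; enrichment-side p
#'     `(1 + #\{null >= obs\}) / (1 + B)`.}
#'   \item{avg_path_difference}{difference in average path length
#'     (connected-pairs convention); two-sided p on `|null| >= |obs|`.}
#' }
#'
#' @param netA,netB \linkS4class{MetaboliteNetwork}s over one universe.
#' @param statistic `"overlap"` or `"avg_path_difference"`.
#' @param B rewiring replicates (>= 100).
#' @param seed integer seed.
#' @param rewire `"both"` or `"one"`.
#' @param nAttempts swap attempts per rewire (default `10 * |E|`).
#' @return A \linkS4class{ComparisonResult} with the corresponding
#'   rewiring-null p-value filled in; the null sample is attached as
#'   attribute `"null"` on the returned object's respective p slot via
#'   `attr(result, "null")`.
#' @export
randomizationTest <- function(netA, netB,
                              statistic = c("overlap",
                                            "avg_path_difference"),
                              B = 1000, seed = 1L,
                              rewire = c("both", "one"),
                              nAttempts = NULL) {
  statistic <- match.arg(statistic)
  rewire <- match.arg(rewire)
  if (B < 100) stop("B must be >= 100")
  cmp <- edgeOverlap(netA, netB)
  universe <- netA@nodes
  nN <- length(universe)
  idxA <- cbind(match(netA@edges$from, universe),
                match(netA@edges$to, universe))
  idxB <- cbind(match(netB@edges$from, universe),
                match(netB@edges$to, universe))
  attA <- nAttempts %||% (10L * nrow(idxA))
  attB <- nAttempts %||% (10L * nrow(idxB))
  keyOf <- function(ix) (pmin(ix[, 1], ix[, 2]) - 1) * nN +
    pmax(ix[, 1], ix[, 2])
  obs <- if (statistic == "overlap") {
    cmp@shared
  } else {
    avgPathFromEdges(idxA, nN) - avgPathFromEdges(idxB, nN)
  }
  degSorted <- function(ix) sort(tabulate(as.vector(ix), nbins = nN))
  dA <- degSorted(idxA); dB <- degSorted(idxB)
  null <- withSeed(seed, {
    vapply(seq_len(B), function(b) {
      ra <- rewire_edges_cpp(idxA, nN, attA)$edges
      rb <- if (rewire == "both") {
        rewire_edges_cpp(idxB, nN, attB)$edges
      } else {
        idxB
      }
      stopifnot(identical(degSorted(ra), dA),
                identical(degSorted(rb), dB))
      if (statistic == "overlap") {
        length(intersect(keyOf(ra), keyOf(rb)))
      } else {
        avgPathFromEdges(ra, nN) - avgPathFromEdges(rb, nN)
      }
    }, numeric(1))
  })
  p <- if (statistic == "overlap") {
    (1 + sum(null >= obs)) / (1 + B)
  } else {
    (1 + sum(abs(null) >= abs(obs))) / (1 + B)
  }
  if (statistic == "overlap") {
    cmp@rewireOverlapP <- p
  } else {
    cmp@pathDifference <- obs
    cmp@rewirePathP <- p
  }
  cmp@nRewires <- as.integer(B)
  cmp@seed <- as.integer(seed)
  attr(cmp, "null") <- null
  cmp
}

setMethod("show", "ComparisonResult", function(object) {
  cat("ComparisonResult ", paste(object@groupA, collapse = "/"), " vs ",
      paste(object@groupB, collapse = "/"), "\n", sep = "")
  cat("  shared ", object@shared, ", A-only ", object@onlyA,
      ", B-only ", object@onlyB, " of ", object@universeSize,
      " candidate pairs\n", sep = "")
  cat("  overlap: ", round(object@overlapPctA, 1), "% of A, ",
      round(object@overlapPctB, 1), "% of B; Fisher p = ",
      signif(object@fisherP, 3), "\n", sep = "")
  if (!is.na(object@rewireOverlapP)) {
    cat("  rewiring-null overlap p = ", signif(object@rewireOverlapP, 3),
        " (B = ", object@nRewires, ")\n", sep = "")
  }
  if (!is.na(object@rewirePathP)) {
    cat("  avg path difference ", signif(object@pathDifference, 3),
        ", rewiring-null p = ", signif(object@rewirePathP, 3), "\n",
        sep = "")
  }
})
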