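#' Pairwise Spearman correlation matrix for one group
#'
#' Spearman rank correlation (average ranks for ties) over all metabolite
#' pairs, using pairwise-complete observations when values are missing.
#' Pairs with fewer than 4 complete observations are recorded as `NA` and
#' excluded from edge calls downstream. The diagonal is set to 1.
#'
#' @param x numeric matrix, samples by metabolites (>= 4 samples).
#' @return symmetric correlation matrix with unit diagonal.
#' @examples
#' spearmanMatrix(cbind(a = 1:5, b = c(1, 3, 2, 5, 4)))["a", "b"]
#' @export
spearmanMatrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 4) stop("need >= 4 samples for correlation analysis")
  r <- .spearman(x)
  cc <- crossprod(!is.na(x))
  r[cc < 4] <- NA_real_
  diag(r) <- 1
  r
}

## Complete matrices take the fast path (rank once, Pearson via BLAS);
## only genuinely missing data pay for pairwise-complete re-ranking.
.spearman <- function(x) {
  if (anyNA(x)) {
    suppressWarnings(cor(x, method = "spearman",
                         use = "pairwise.complete.obs"))
  } else {
    suppressWarnings(cor(apply(x, 2, rank)))
  }
}

#' Pooled permutation null distribution of Spearman correlations
#'
#' The permutation scheme shuffles the whole group matrix -- all cells at
#' once, destroying both sample and metabolite structure (`"global"`) --
#' recomputes the full Spearman matrix, and pools every off-diagonal
#' coefficient across all `B` shuffles into one null sample. A
#' `"per_column"` scheme that permutes each metabolite independently
#' (preserving marginal distributions) is available as an alternative.
#'
#' @param x numeric matrix, samples by metabolites.
#' @param B number of shuffles (>= 100; p-value resolution is too coarse
#'   below that).
#' @param seed integer seed.
#' @param scheme `"global"` (default) or `"per_column"`.
#' @return list of class `"ShuffleNull"`: `null` (pooled numeric vector),
#'   `B`, `scheme`, `n`, `m`.
#' @export
shuffleNull <- function(x, B = 1000, seed = 1L,
                        scheme = c("global", "per_column")) {
  scheme <- match.arg(scheme)
  x <- as.matrix(x)
  if (B < 100) stop("B must be >= 100: fewer shuffles give too coarse a p-value resolution")
  obs <- x[!is.na(x)]
  if (length(unique(obs)) < 2) {
    stop("degenerate input: the group matrix is constant, correlations are undefined")
  }
  m <- ncol(x)
  ut <- upper.tri(matrix(0, m, m))
  null <- withSeed(seed, {
    vapply(seq_len(B), function(b) {
      xs <- if (scheme == "global") {
        matrix(sample(x), nrow(x), m)
      } else {
        apply(x, 2, sample)
      }
      rn <- .spearman(xs)
      rn[ut]
    }, numeric(sum(ut)))
  })
  null <- as.vector(null)
  null <- null[is.finite(null)]
  structure(list(null = null, B = as.integer(B), scheme = scheme,
                 n = nrow(x), m = m),
            class = "ShuffleNull")
}

#' Empirical two-sided p-values against a permutation null
#'
#' `p = (1 + #\{|r_null| >= |r_obs|\}) / (1 + N_null)`, with add-one
#' smoothing so p is never zero and ties counted as exceedances.
#'
#' @param rObs numeric vector (or matrix) of observed correlations.
#' @param null numeric vector of null correlations, or a `"ShuffleNull"`.
#' @return empirical p-values with the shape of `rObs` (`NA` in, `NA` out).
#' @examples
#' empiricalP(0.4, c(-0.5, 0.1, 0.4)) # (1 + 2) / (1 + 3)
#' @export
empiricalP <- function(rObs, null) {
  if (inherits(null, "ShuffleNull")) null <- null$null
  a <- sort(abs(null))
  N <- length(a)
  v <- abs(rObs)
  p <- rep(NA_real_, length(v))
  ok <- !is.na(v)
  ## findInterval(t, a, left.open) counts null values strictly below t
  below <- findInterval(v[ok], a, left.open = TRUE)
  p[ok] <- (1 + (N - below)) / (1 + N)
  if (is.matrix(rObs)) p <- matrix(p, nrow(rObs), ncol(rObs),
                                   dimnames = dimnames(rObs))
  p
}

#' Correlation analysis of one cultivar/stage group
#'
#' Runs the full per-group procedure: Spearman matrix, permutation null
#' ([shuffleNull()]), empirical p-values and BH adjustment over the
#' `choose(m, 2)` off-diagonal family.
#'
#' @param x numeric matrix, samples by metabolites, for one group.
#' @param group character(2), cultivar and stage labels.
#' @param B shuffles for the null (default 1000).
#' @param seed integer seed.
#' @param scheme permutation scheme, see [shuffleNull()].
#' @param pooled if `TRUE` (default) one pooled null sample serves every
#'   pair; if `FALSE` each pair is compared only against its own `B` null
#'   coefficients.
#' @return A \linkS4class{CorrelationResult}.
#' @export
correlationGroup <- function(x, group = c(NA, NA), B = 1000, seed = 1L,
                             scheme = c("global", "per_column"),
                             pooled = TRUE) {
  scheme <- match.arg(scheme)
  x <- as.matrix(x)
  r <- spearmanMatrix(x)
  m <- ncol(r)
  ut <- upper.tri(r)
  if (pooled) {
    nul <- shuffleNull(x, B = B, seed = seed, scheme = scheme)
    pEmp <- empiricalP(r, nul)
    nullSize <- length(nul$null)
  } else {
    if (B < 100) stop("B must be >= 100")
    obs <- x[!is.na(x)]
    if (length(unique(obs)) < 2) {
      stop("degenerate input: the group matrix is constant")
    }
    cnt <- matrix(0, m, m)
    den <- matrix(0, m, m)
    withSeed(seed, {
      for (b in seq_len(B)) {
        xs <- if (scheme == "global") {
          matrix(sample(x), nrow(x), m)
        } else {
          apply(x, 2, sample)
        }
        rn <- .spearman(xs)
        hit <- !is.na(rn) & !is.na(r) & abs(rn) >= abs(r)
        cnt <- cnt + hit
        den <- den + !is.na(rn)
      }
    })
    pEmp <- (1 + cnt) / (1 + den)
    pEmp[is.na(r)] <- NA_real_
    nullSize <- as.integer(B)
  }
  diag(pEmp) <- NA_real_
  pAdj <- matrix(NA_real_, m, m, dimnames = dimnames(r))
  pAdj[ut] <- bhAdjust(pEmp[ut])
  pAdj[lower.tri(pAdj)] <- t(pAdj)[lower.tri(pAdj)]
  pEmp[lower.tri(pEmp)] <- t(pEmp)[lower.tri(pEmp)]
  new("CorrelationResult", group = as.character(group), r = r,
      pEmp = pEmp, pAdj = pAdj, nShuffles = as.integer(B),
      nullSize = as.integer(min(nullSize, .Machine$integer.max)),
      nSamples = nrow(x))
}

#' Build the signed metabolite network from a correlation result
#'
#' An edge connects two metabolites when `|r| > rMin` (strict) and the
#' BH-adjusted permutation p-value is below `alpha`. Isolated nodes are
#' retained in the node universe. Pairs whose correlation could not be
#' computed are never edges.
#'
#' @param corr a \linkS4class{CorrelationResult}.
#' @param rMin correlation threshold (default 0.75).
#' @param alpha FDR level on adjusted p-values (default 0.05, the
#'   significance level used for all tests in the pipeline).
#' @return A \linkS4class{MetaboliteNetwork}.
#' @export
buildNetwork <- function(corr, rMin = 0.75, alpha = 0.05) {
  stopifnot(is(corr, "CorrelationResult"))
  r <- corr@r
  nodes <- colnames(r)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[ut]
  pa <- corr@pAdj[ut]
  pe <- corr@pEmp[ut]
  keep <- !is.na(rv) & abs(rv) > rMin & !is.na(pa) & pa < alpha
  edges <- data.frame(
    from = nodes[ut[keep, 1]], to = nodes[ut[keep, 2]],
    r = rv[keep], sign = sign(rv[keep]),
    p_emp = pe[keep], p_adj = pa[keep],
    stringsAsFactors = FALSE)
  new("MetaboliteNetwork", group = corr@group, nodes = nodes,
      edges = edges, rMin = rMin, alpha = alpha)
}

#' @rdname berrynet-generics
#' @export
setMethod("correlationMatrix", "CorrelationResult", function(object) object@r)

#' @rdname berrynet-generics
#' @export
setMethod("adjustedPValues", "CorrelationResult", function(object) object@pAdj)

setMethod("show", "CorrelationResult", function(object) {
  cat("CorrelationResult for group", paste(object@group, collapse = "/"),
      "\n")
  cat("  ", ncol(object@r), " metabolites, ", object@nSamples,
      " samples, ", object@nShuffles, " shuffles\n", sep = "")
})

#' @rdname berrynet-generics
#' @export
setMethod("networkEdges", "MetaboliteNetwork", function(object) object@edges)

#' @rdname berrynet-generics
#' @export
setMethod("networkNodes", "MetaboliteNetwork", function(object) object@nodes)

#' @rdname berrynet-generics
#' @export
setMethod("nodeDegrees", "MetaboliteNetwork", function(object) {
  d <- setNames(rep(0L, length(object@nodes)), object@nodes)
  if (nrow(object@edges)) {
    t1 <- table(object@edges$from)
    t2 <- table(object@edges$to)
    d[names(t1)] <- d[names(t1)] + as.integer(t1)
    d[names(t2)] <- d[names(t2)] + as.integer(t2)
  }
  d
})

#' @describeIn berrynet-generics convert a MetaboliteNetwork to an igraph
#'   graph (unweighted, undirected; isolated nodes kept; edge attributes
#'   `r` and `sign`).
#' @export
setMethod("asIgraph", "MetaboliteNetwork", function(object, ...) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(object@nodes), name = object@nodes)
  if (nrow(object@edges)) {
    idx <- rbind(match(object@edges$from, object@nodes),
                 match(object@edges$to, object@nodes))
    g <- igraph::add_edges(g, as.vector(idx),
                           r = object@edges$r, sign = object@edges$sign)
  }
  g
})

setMethod("show", "MetaboliteNetwork", function(object) {
  d <- nodeDegrees(object)
  cat("MetaboliteNetwork", paste(object@group, collapse = "/"), "\n")
  cat("  ", length(object@nodes), " nodes (", sum(d > 0), " connected, ",
      sum(d == 0), " isolated), ", nrow(object@edges), " edges\n", sep = "")
  cat("  thresholds: |r| > ", object@rMin, ", FDR < ", object@alpha, "\n",
      sep = "")
})

#' Construct a MetaboliteNetwork from an explicit edge list
#'
#' Convenience constructor used for toy graphs, comparisons and tests.
#'
#' @param nodes character vector, the node universe.
#' @param edges data.frame with columns `from` and `to` (optionally `r`);
#'   or a 2-column matrix.
#' @param group character(2) group labels.
#' @param rMin,alpha thresholds to record.
#' @return A \linkS4class{MetaboliteNetwork}.
#' @export
metaboliteNetwork <- function(nodes, edges, group = c("toy", "toy"),
                              rMin = 0, alpha = 1) {
  if (is.matrix(edges)) {
    edges <- data.frame(from = edges[, 1], to = edges[, 2],
                        stringsAsFactors = FALSE)
  }
  if (is.null(edges$r)) edges$r <- rep(1, nrow(edges))
  edges$sign <- sign(edges$r)
  new("MetaboliteNetwork", group = as.character(group),
      nodes = as.character(nodes), edges = edges,
      rMin = rMin, alpha = alpha)
}
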