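#' Summarize the topology of a metabolite network
#'
#' One summary row per network in the conventions used throughout the
#' pipeline:
#' \itemize{
#'   \item `connected_nodes` / `isolated_nodes`: degree >= 1 / degree 0
#'     over the full node universe (the two always sum to the universe
#'     size);
#'   \item `edges`: edge count;
#'   \item `connected_components`: components with >= 2 nodes (isolated
#'     nodes are reported separately, not as components);
#'   \item `diameter` / `average_path_length`: maximum / mean shortest-path
#'     length over connected node pairs only (infinite distances of a
#'     disconnected graph are excluded); 0 with `no_paths = TRUE` when the
#'     network has no edges;
#'   \item `density`: `edges / (N (N - 1) / 2)` with `N` the full universe
#'     size, isolated nodes included;
#'   \item `cluster_coefficient`: mean node clustering coefficient over
#'     connected nodes by default (see [nodeClustering()]); set
#'     `clusteringOver = "universe"` to average over all nodes.
#' }
#'
#' @param network a \linkS4class{MetaboliteNetwork}.
#' @param clusteringOver `"connected"` (default) or `"universe"`.
#' @return one-row data.frame with the fields above plus `cultivar`,
#'   `stage` and `no_paths`.
#' @export
summarizeTopology <- function(network,
                              clusteringOver = c("connected", "universe")) {
  clusteringOver <- match.arg(clusteringOver)
  g <- asIgraph(network)
  N <- length(network@nodes)
  deg <- igraph::degree(g)
  nEdges <- igraph::ecount(g)
  comp <- igraph::components(g)
  nComp <- sum(comp$csize >= 2)
  if (nEdges > 0) {
    diam <- igraph::diameter(g, unconnected = TRUE)
    apl <- igraph::mean_distance(g, unconnected = TRUE)
    noPaths <- FALSE
  } else {
    diam <- 0; apl <- 0; noPaths <- TRUE
  }
  cn <- nodeClustering(network)
  cc <- if (clusteringOver == "connected") {
    if (any(deg > 0)) mean(cn[deg > 0]) else 0
  } else {
    mean(cn)
  }
  data.frame(
    cultivar = network@group[1], stage = network@group[2],
    connected_nodes = sum(deg > 0), isolated_nodes = sum(deg == 0),
    edges = nEdges, connected_components = nComp,
    diameter = diam, average_path_length = apl,
    density = nEdges / (N * (N - 1) / 2),
    cluster_coefficient = cc, no_paths = noPaths,
    stringsAsFactors = FALSE)
}

#' Shortest-path betweenness centrality
#'
#' Raw betweenness (number of shortest paths between other node pairs
#' passing through each node, fractionally counted over equally short
#' paths) on the unweighted, unsigned graph, together with a normalized
#' variant dividing by `(Nc - 1)(Nc - 2) / 2` within each connected
#' component of size `Nc` (0 for nodes in components smaller than 3).
#'
#' @param network a \linkS4class{MetaboliteNetwork}.
#' @return data.frame: `node`, `degree`, `betweenness`,
#'   `betweenness_normalized`.
#' @export
nodeBetweenness <- function(network) {
  g <- asIgraph(network)
  btw <- igraph::betweenness(g, directed = FALSE)
  comp <- igraph::components(g)
  csize <- comp$csize[comp$membership]
  denom <- (csize - 1) * (csize - 2) / 2
  norm <- ifelse(denom > 0, btw / denom, 0)
  data.frame(node = network@nodes,
             degree = as.integer(igraph::degree(g)),
             betweenness = unname(btw),
             betweenness_normalized = unname(norm),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Node clustering coefficients
#'
#' `Cn = 2 T(n) / (deg(n) (deg(n) - 1))` with `T(n)` the number of
#' triangles through `n`; nodes of degree < 2 get `Cn = 0`.
#'
#' @param network a \linkS4class{MetaboliteNetwork}.
#' @return named numeric vector of `Cn` per node.
#' @export
nodeClustering <- function(network) {
  g <- asIgraph(network)
  cn <- igraph::transitivity(g, type = "local", isolates = "zero")
  setNames(ifelse(is.nan(cn), 0, cn), network@nodes)
}

#' Centrality table for a network
#'
#' Degree, raw and normalized betweenness, and clustering coefficient for
#' every node of the universe.
#'
#' @param network a \linkS4class{MetaboliteNetwork}.
#' @return data.frame: `node`, `degree`, `betweenness`,
#'   `betweenness_normalized`, `clustering`.
#' @export
centralityTable <- function(network) {
  out <- nodeBetweenness(network)
  out$clustering <- unname(nodeClustering(network))
  out
}

#' Fit power-law and exponential models to the cumulative degree
#' distribution
#'
#' Builds the empirical upper-tail distribution `P(K >= k)` over the
#' positive degrees of the network (isolated nodes excluded by default),
#' fits `c * k^(-gamma)` (power law) and `c * exp(-lambda k)`
#' (exponential) by nonlinear least squares, and selects between them by
#' `AIC = n log(RSS / n) + 2 p`. Starting values come from the log--log
#' and semi-log linear regressions. Networks with fewer than 5 distinct
#' positive degrees are flagged unfit-able.
#'
#' @param network a \linkS4class{MetaboliteNetwork}, or an integer vector
#'   of node degrees.
#' @param excludeZero drop degree-0 nodes before building the CCDF
#'   (default `TRUE`).
#' @return list of class `"DegreeFitResult"`: `k`, `ccdf`, `fits` (per
#'   model: `params`, `rss`, `aic`, `converged`), `delta_aic`,
#'   `akaike_weights`, `selected` (`"power_law"`, `"exponential"` or
#'   `NA`), `fitable`.
#' @export
fitDegreeDistribution <- function(network, excludeZero = TRUE) {
  deg <- if (is(network, "MetaboliteNetwork")) {
    as.integer(nodeDegrees(network))
  } else {
    as.integer(network)
  }
  if (excludeZero) deg <- deg[deg > 0]
  ks <- sort(unique(deg))
  out <- list(k = ks, ccdf = NULL, fits = NULL, delta_aic = NA_real_,
              akaike_weights = c(power_law = NA_real_,
                                 exponential = NA_real_),
              selected = NA_character_, fitable = FALSE)
  class(out) <- "DegreeFitResult"
  if (length(ks) < 5) return(out)
  ccdf <- vapply(ks, function(k) mean(deg >= k), numeric(1))
  out$ccdf <- ccdf
  n <- length(ks)

  fit1 <- function(formula, start) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data.frame(k = ks, y = ccdf),
                        start = start,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) {
      list(params = start, rss = NA_real_, aic = NA_real_,
           converged = FALSE)
    } else {
      rss <- sum(residuals(fit)^2)
      list(params = as.list(coef(fit)), rss = rss,
           aic = n * log(rss / n) + 2 * 2, converged = TRUE)
    }
  }
  ## starting values from linearized fits
  lp <- lm(log(ccdf) ~ log(ks))
  le <- lm(log(ccdf) ~ ks)
  startP <- list(c = exp(coef(lp)[1]), gamma = -coef(lp)[2])
  startE <- list(c = exp(coef(le)[1]), lambda = -coef(le)[2])
  startP$gamma <- max(startP$gamma, 1e-3)
  startE$lambda <- max(startE$lambda, 1e-3)
  pw <- fit1(y ~ c * k^(-gamma), startP)
  ex <- fit1(y ~ c * exp(-lambda * k), startE)
  out$fits <- list(power_law = pw, exponential = ex)
  out$fitable <- TRUE
  aics <- c(power_law = pw$aic, exponential = ex$aic)
  if (all(is.finite(aics))) {
    out$delta_aic <- aics - min(aics)
    w <- exp(-0.5 * out$delta_aic)
    out$akaike_weights <- w / sum(w)
    out$selected <- names(which.min(aics))
  } else if (any(is.finite(aics))) {
    out$selected <- names(aics)[is.finite(aics)][1]
    out$akaike_weights <- setNames(as.numeric(is.finite(aics)),
                                   names(aics))
  }
  out
}
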