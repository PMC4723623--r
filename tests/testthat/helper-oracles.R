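## Independent brute-force oracles and small fixture builders used across
## the suite. Everything here is deliberately naive (Floyd-Warshall,
## exhaustive enumeration, direct summation) and shares no code with the
## package's implementation paths.

## ---- graph fixtures ------------------------------------------------------

## adjacency matrix (logical, symmetric, no diagonal) from a network
adjacencyOf <- function(net) {
  nodes <- networkNodes(net)
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  e <- networkEdges(net)
  if (nrow(e)) {
    ia <- match(e$from, nodes); ib <- match(e$to, nodes)
    A[cbind(ia, ib)] <- TRUE
    A[cbind(ib, ia)] <- TRUE
  }
  A
}

## Erdos-Renyi toy network over n nodes
randomToyNetwork <- function(n, p, seed) {
  nodes <- sprintf("n%02d", seq_len(n))
  set.seed(seed)
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  metaboliteNetwork(nodes, pairs[keep, , drop = FALSE])
}

## small MetaboliteExperiment from a samples x metabolites matrix
toyExperiment <- function(values, stage = NULL, cultivar = NULL,
                          classes = NULL, processing = "raw",
                          stageOrder = berryStages()) {
  values <- as.matrix(values)
  n <- nrow(values); m <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- sprintf("m%02d", 1:m)
  if (is.null(stage)) stage <- rep("FLW", n)
  if (is.null(cultivar)) cultivar <- rep("CS", n)
  if (is.null(classes)) classes <- rep("sugar", m)
  sid <- sprintf("s%02d", 1:n)
  rownames(values) <- sid
  MetaboliteExperiment(
    values,
    samples = data.frame(sample_id = sid, cultivar = cultivar,
                         stage = stage, year = 1L),
    metabolites = data.frame(metabolite_id = colnames(values),
                             name = colnames(values), class = classes),
    stageOrder = stageOrder, processing = processing)
}

## ---- shortest-path oracles (Floyd-Warshall + path counting) --------------

oracleDistances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A] <- 1
  for (k in 1:n) {
    Dk <- outer(D[, k], D[k, ], "+")
    D <- pmin(D, Dk)
  }
  D
}

oraclePathStats <- function(A) {
  D <- oracleDistances(A)
  v <- D[upper.tri(D)]
  v <- v[is.finite(v) & v > 0]
  if (!length(v)) return(list(diameter = 0, apl = 0))
  list(diameter = max(v), apl = mean(v))
}

## number of shortest paths between every pair, given distances
oraclePathCounts <- function(A, D) {
  n <- nrow(A)
  cnt <- matrix(0, n, n)
  diag(cnt) <- 1
  maxd <- max(D[is.finite(D)])
  for (d in seq_len(maxd)) {
    for (s in 1:n) {
      targets <- which(D[s, ] == d)
      for (t in targets) {
        preds <- which(A[, t] & D[s, ] == d - 1)
        cnt[s, t] <- sum(cnt[s, preds])
      }
    }
  }
  cnt
}

oracleBetweenness <- function(A) {
  n <- nrow(A)
  D <- oracleDistances(A)
  cnt <- oraclePathCounts(A, D)
  btw <- numeric(n)
  for (v in 1:n) {
    acc <- 0
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(D[s, t])) next
      if (D[s, v] + D[v, t] == D[s, t]) {
        acc <- acc + cnt[s, v] * cnt[v, t] / cnt[s, t]
      }
    }
    btw[v] <- acc
  }
  btw
}

oracleClustering <- function(A) {
  n <- nrow(A)
  M <- A * 1
  tri <- diag(M %*% M %*% M) / 2
  deg <- rowSums(M)
  ifelse(deg < 2, 0, 2 * tri / (deg * (deg - 1)))
}

oracleComponents <- function(A) {
  n <- nrow(A)
  seen <- rep(FALSE, n)
  sizes <- integer(0)
  for (s in 1:n) {
    if (seen[s]) next
    stack <- s; comp <- integer(0)
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      comp <- c(comp, v)
      stack <- c(stack, which(A[v, ] & !seen))
    }
    sizes <- c(sizes, length(comp))
  }
  sizes
}

## ---- statistics oracles --------------------------------------------------

## step-up BH from the definition
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

## hypergeometric upper tail by direct summation
oracleHyperTail <- function(shared, nA, nB, M) {
  ks <- shared:min(nA, nB)
  sum(dhyper(ks, nA, M - nA, nB))
}

## all permutations of 1..n (n <= 7)
allPerms <- function(v) {
  if (length(v) <= 1) return(matrix(v, nrow = 1))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], allPerms(v[-i]))
  }))
}

## exact null distribution of Spearman's r for sample size n (no ties)
exactSpearmanNull <- function(n) {
  P <- allPerms(seq_len(n))
  d2 <- rowSums((P - matrix(seq_len(n), nrow(P), n, byrow = TRUE))^2)
  1 - 6 * d2 / (n * (n^2 - 1))
}
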