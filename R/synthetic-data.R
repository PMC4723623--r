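#' Describe a berry-development experiment layout
#'
#' Captures the study design the generator emulates: two cultivars sampled
#' over six developmental stages with around ten biological replicates per
#' group split evenly over two field seasons, and 115 annotated metabolites
#' in eight chemical classes.
#'
#' @param cultivars character, cultivar labels.
#' @param stages character, ordered developmental stage labels.
#' @param replicates integer, biological samples per (cultivar, stage)
#'   group (>= 3).
#' @param years integer, seasons over which replicates are split evenly.
#' @param nMetabolites integer, total metabolites.
#' @param classCounts named integer vector mapping chemical class to
#'   metabolite count; must sum to `nMetabolites`.
#' @param seed integer master seed for everything derived from the design.
#' @return A validated list of class `"ExperimentDesign"`.
#' @examples
#' d <- experimentDesign()
#' d$replicates
#' @export
experimentDesign <- function(cultivars = c("CS", "ME"),
                             stages = berryStages(),
                             replicates = 10L,
                             years = 2L,
                             nMetabolites = NULL,
                             classCounts = defaultClassCounts(),
                             seed = 1L) {
  if (is.null(nMetabolites)) nMetabolites <- sum(classCounts)
  if (sum(classCounts) != nMetabolites) {
    stop("class counts sum to ", sum(classCounts),
         " but nMetabolites is ", nMetabolites)
  }
  if (anyDuplicated(stages)) stop("stages must be unique")
  if (replicates < 3) stop("replicates per group must be >= 3")
  if (years < 1 || replicates %% years != 0) {
    stop("replicates must split evenly across years")
  }
  structure(
    list(cultivars = cultivars, stages = stages,
         replicates = as.integer(replicates), years = as.integer(years),
         nMetabolites = as.integer(nMetabolites),
         classCounts = classCounts, seed = as.integer(seed)),
    class = "ExperimentDesign"
  )
}

#' Default metabolite class composition
#'
#' The eight chemical classes of the profiled berry metabolome and their
#' member counts (total 115).
#' @return named integer vector.
#' @export
defaultClassCounts <- function() {
  c("amino acid" = 19L, "fatty acid" = 4L, "acid" = 22L, "flavonoid" = 3L,
    "miscellaneous" = 11L, "sugar" = 19L, "unclassified" = 17L,
    "unknown" = 20L)
}

#' Default per-class developmental trend (log2 units per stage step)
#'
#' Sugars accumulate during ripening while amino acids decline; all other
#' classes are flat by default.
#' @return named numeric vector of log2 slopes per stage index.
#' @export
defaultTrendSpec <- function() c("sugar" = 1, "amino acid" = -0.5)

#' Plant a ground-truth correlation network for one group
#'
#' Constructs the edge set that [sampleGroupMatrix()] will realize as
#' correlated intensities. Three generative models are supported:
#' \describe{
#'   \item{hub}{`nHubs` hub metabolites, each connected to a disjoint set
#'     of spokes (heavy-tailed degree distribution, emulating the
#'     scale-free organization of metabolite networks).}
#'   \item{block}{complete subgraphs over blocks of the given sizes
#'     (shared-factor modules); block edges are positive by construction.}
#'   \item{random}{Erdős–Rényi edge placement with `nEdges` expected
#'     edges.}
#' }
#'
#' @param group character(2), cultivar and stage labels.
#' @param nodes character vector of metabolite ids (>= 3).
#' @param model one of `"hub"`, `"block"`, `"random"`.
#' @param params list of model parameters: `nHubs`, `hubDegree` (hub);
#'   `blockSizes` (block); `nEdges` (random); all models honor `targetR`
#'   (target absolute Spearman correlation, in (0,1)) and `negFraction`
#'   (fraction of negative-sign edges; forced 0 for block).
#' @param seed integer seed.
#' @return A list of class `"PlantedNetwork"` with the group id, node set,
#'   edge table (`from`, `to`, `sign`, `target_r`), model tag and params.
#' @examples
#' pn <- makePlantedNetwork(c("CS", "FS"), paste0("m", 1:10), "hub",
#'   list(nHubs = 1, targetR = 0.9), seed = 7)
#' nrow(pn$edges) # star over 10 nodes
#' @export
makePlantedNetwork <- function(group, nodes, model,
                               params = list(), seed = 1L) {
  if (length(nodes) < 3) stop("need at least 3 nodes")
  if (anyDuplicated(nodes)) stop("node ids must be unique")
  if (!model %in% c("hub", "block", "random")) {
    stop("invalid model tag '", model, "' (use hub, block or random)")
  }
  targetR <- params$targetR %||% 0.9
  if (targetR <= 0 || targetR >= 1) stop("targetR must be in (0, 1)")
  negFraction <- params$negFraction %||% 0
  m <- length(nodes)

  edges <- withSeed(seed, {
    if (model == "hub") {
      nHubs <- params$nHubs %||% 1L
      if (nHubs >= m) stop("nHubs must be smaller than the node count")
      ord <- sample(nodes)
      hubs <- ord[seq_len(nHubs)]
      rest <- ord[-seq_len(nHubs)]
      hubDegree <- params$hubDegree %||% ceiling(length(rest) / nHubs)
      if (nHubs * hubDegree > length(rest) + (nHubs - 1)) {
        hubDegree <- floor(length(rest) / nHubs)
      }
      owner <- rep(hubs, length.out = length(rest))
      take <- unlist(lapply(hubs, function(h) {
        sp <- rest[owner == h]
        head(sp, hubDegree)
      }))
      ownerTaken <- rep(hubs, times = vapply(hubs, function(h) {
        length(head(rest[owner == h], hubDegree))
      }, integer(1)))
      data.frame(from = ownerTaken, to = take, stringsAsFactors = FALSE)
    } else if (model == "block") {
      blockSizes <- params$blockSizes %||% rep(5L, floor(m / 5))
      if (sum(blockSizes) > m) stop("block sizes exceed the node count")
      negFraction <- 0
      ord <- sample(nodes)
      idx <- 0L
      do.call(rbind, lapply(blockSizes, function(b) {
        members <- ord[idx + seq_len(b)]
        idx <<- idx + as.integer(b)
        if (b < 2) return(NULL)
        pairs <- combn(members, 2)
        data.frame(from = pairs[1, ], to = pairs[2, ],
                   stringsAsFactors = FALSE)
      }))
    } else { # random
      maxEdges <- choose(m, 2)
      nEdges <- params$nEdges %||% round(0.05 * maxEdges)
      if (nEdges > maxEdges) {
        stop("requested ", nEdges, " edges but only ", maxEdges,
             " pairs exist")
      }
      p <- nEdges / maxEdges
      pairs <- combn(nodes, 2)
      keep <- runif(ncol(pairs)) < p
      data.frame(from = pairs[1, keep], to = pairs[2, keep],
                 stringsAsFactors = FALSE)
    }
  })
  if (is.null(edges)) edges <- data.frame(from = character(), to = character())
  edges$sign <- rep(1, nrow(edges))
  if (negFraction > 0 && nrow(edges)) {
    nneg <- round(negFraction * nrow(edges))
    edges$sign <- withSeed(seed + 1L, {
      s <- rep(1, nrow(edges))
      s[sample(nrow(edges), nneg)] <- -1
      s
    })
  }
  edges$target_r <- rep(targetR, nrow(edges))
  rownames(edges) <- NULL
  structure(
    list(group = group, nodes = nodes, edges = edges, model = model,
         params = c(params, list(targetR = targetR,
                                 negFraction = negFraction))),
    class = "PlantedNetwork"
  )
}

#' Draw one group's intensity sub-table from a planted network
#'
#' Latent variables are Gaussian on the log2 scale: hub spokes are noisy
#' (possibly sign-flipped) copies of their hub, block members share a
#' common factor, and arbitrary edge sets are realized through the nearest
#' positive-definite correlation matrix. Target absolute Spearman
#' correlations are met through the bivariate-normal relation
#' `rho = 2 sin(pi r_s / 6)` (see [spearmanToPearson()]); the final
#' exponentiation is monotone, so rank correlations are preserved.
#'
#' @param planted a `"PlantedNetwork"`.
#' @param nSamples integer, replicates to draw (>= 3).
#' @param noiseSd positive scalar, marginal SD of the latent log2 values.
#' @param seed integer seed.
#' @param baselineLog2 numeric scalar or per-metabolite named vector added
#'   on the log2 scale (metabolite abundance level, plus any stage trend).
#' @return numeric matrix, `nSamples` rows by `length(planted$nodes)`
#'   columns of strictly positive intensities.
#' @examples
#' pn <- makePlantedNetwork(c("CS", "FS"), paste0("m", 1:6), "hub",
#'   list(nHubs = 1, targetR = 0.95), seed = 3)
#' x <- sampleGroupMatrix(pn, nSamples = 10, seed = 3)
#' dim(x)
#' @export
sampleGroupMatrix <- function(planted, nSamples, noiseSd = 1, seed = 1L,
                              baselineLog2 = 10) {
  stopifnot(inherits(planted, "PlantedNetwork"))
  if (nSamples < 3) stop("nSamples must be >= 3")
  if (noiseSd <= 0) stop("noiseSd must be positive")
  nodes <- planted$nodes
  m <- length(nodes)
  edges <- planted$edges
  rho <- spearmanToPearson(edges$target_r) * edges$sign

  z <- withSeed(seed, {
    z0 <- matrix(rnorm(nSamples * m), nSamples, m, dimnames = list(NULL, nodes))
    if (planted$model == "hub") {
      ## spokes = rho * hub + sqrt(1 - rho^2) * own noise
      for (k in seq_len(nrow(edges))) {
        h <- edges$from[k]; s <- edges$to[k]; r <- rho[k]
        z0[, s] <- r * z0[, h] + sqrt(1 - r^2) * z0[, s]
      }
      z0
    } else if (planted$model == "block") {
      ## shared factor per block; pairwise latent correlation = rho
      comp <- edgeComponents(nodes, edges)
      for (members in comp) {
        if (length(members) < 2) next
        r <- spearmanToPearson(
          edges$target_r[edges$from %in% members][1])
        f <- rnorm(nSamples)
        z0[, members] <- sqrt(r) * f +
          sqrt(1 - r) * z0[, members, drop = FALSE]
      }
      z0
    } else {
      ## generic: target correlation matrix, projected to the nearest
      ## positive-definite correlation matrix when needed
      sigma <- diag(m)
      dimnames(sigma) <- list(nodes, nodes)
      if (nrow(edges)) {
        ia <- match(edges$from, nodes); ib <- match(edges$to, nodes)
        sigma[cbind(ia, ib)] <- rho
        sigma[cbind(ib, ia)] <- rho
      }
      ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < 1e-8) {
        sigma <- as.matrix(Matrix::nearPD(sigma, corr = TRUE)$mat)
      }
      z0 %*% chol(sigma)
    }
  })

  if (length(baselineLog2) == 1L) {
    baselineLog2 <- setNames(rep(baselineLog2, m), nodes)
  }
  log2vals <- sweep(noiseSd * z, 2, baselineLog2[nodes], "+")
  x <- 2^log2vals
  rownames(x) <- NULL
  x
}

## Connected components of a planted edge list (used for block factors).
edgeComponents <- function(nodes, edges) {
  parent <- setNames(seq_along(nodes), nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(edges))) {
    a <- find(match(edges$from[k], nodes))
    b <- find(match(edges$to[k], nodes))
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_along(nodes), find, numeric(1))
  comp <- split(nodes, roots)
  comp[vapply(comp, length, integer(1)) >= 2]
}

#' Generate a full synthetic berry-development dataset
#'
#' Produces the complete experiment: one intensity sub-table per
#' (cultivar, stage) group drawn from that group's planted network,
#' per-class developmental trends added on the log2 scale, and sample and
#' metabolite annotation tables. Purely constructive and fully reproducible
#' from the design seed.
#'
#' @param design an [experimentDesign()].
#' @param trendSpec named numeric vector of log2 slopes per chemical class
#'   and stage step (classes absent from the vector are flat).
#' @param networkSpecs `"default"` (or `NULL`): a conserved core
#'   sub-network shared by all groups plus group-specific hubs;
#'   `"none"`: no planted correlations; a single spec
#'   `list(model =, params =)` recycled to every group; or a named list
#'   keyed `<cultivar>.<stage>` with one spec (or `"PlantedNetwork"`) per
#'   group.
#' @param noiseSd positive scalar, replicate SD on the log2 scale.
#' @param missingRate fraction of entries deleted completely at random.
#' @return A list of class `"SyntheticDataset"`: `experiment`
#'   (a raw \linkS4class{MetaboliteExperiment}), `planted` (list of
#'   planted networks keyed by group), `trendSpec`, `design`.
#' @examples
#' ds <- generateExperiment(experimentDesign(nMetabolites = 10,
#'   classCounts = c(sugar = 5, `amino acid` = 5), replicates = 4, seed = 2))
#' dim(intensityMatrix(ds$experiment))
#' @export
generateExperiment <- function(design = experimentDesign(),
                               trendSpec = defaultTrendSpec(),
                               networkSpecs = NULL,
                               noiseSd = 1,
                               missingRate = 0) {
  stopifnot(inherits(design, "ExperimentDesign"))
  ids <- sprintf("m%03d", seq_len(design$nMetabolites))
  classes <- rep(names(design$classCounts), times = design$classCounts)
  metabolites <- data.frame(metabolite_id = ids, name = ids,
                            class = classes, stringsAsFactors = FALSE)
  groups <- expand.grid(stage = design$stages, cultivar = design$cultivars,
                        stringsAsFactors = FALSE)[, c("cultivar", "stage")]
  keys <- paste(groups$cultivar, groups$stage, sep = ".")

  if (is.null(networkSpecs)) networkSpecs <- "default"
  specFor <- function(key) {
    if (identical(networkSpecs, "none")) return("none")
    if (identical(networkSpecs, "default")) return("default")
    if (!is.null(networkSpecs$model)) return(networkSpecs)
    if (is.null(networkSpecs[[key]])) {
      stop("no network spec for group ", key)
    }
    networkSpecs[[key]]
  }

  ## Default planted structure: a conserved "core" sub-network shared by
  ## every (cultivar, stage) group -- emulating correlations conserved
  ## across development -- plus group-specific hubs over the remaining
  ## metabolites. Core and group nodes are disjoint, so hub-and-spoke
  ## assignments never conflict.
  defaultPlanted <- function(cv, st, gseed) {
    m <- design$nMetabolites
    coreN <- max(3L, round(m / 3))
    coreNodes <- ids[seq_len(coreN)]
    restNodes <- ids[-seq_len(coreN)]
    par <- function(nn, r) list(nHubs = max(1L, nn %/% 15L),
                                targetR = r, negFraction = 0.25)
    ## the conserved core is planted stronger than the group-specific
    ## hubs: with BH over choose(115, 2) pairs the binding correlation is
    ## ~0.87 at n = 10, and the core's purpose is to be recoverable in
    ## every stage network
    core <- makePlantedNetwork(c(cv, st), coreNodes, "hub",
                               par(coreN, 0.9),
                               seed = groupSeed(design$seed, "core"))
    edges <- core$edges
    if (length(restNodes) >= 3) {
      grp <- makePlantedNetwork(c(cv, st), restNodes, "hub",
                                par(length(restNodes), 0.85), seed = gseed)
      edges <- rbind(edges, grp$edges)
    }
    structure(list(group = c(cv, st), nodes = ids, edges = edges,
                   model = "hub", params = par(m, 0.85)),
              class = "PlantedNetwork")
  }

  ## metabolite baselines shared across groups (so the experiment-wide
  ## median normalization is meaningful)
  baseline <- withSeed(groupSeed(design$seed, "baseline"), {
    setNames(rnorm(design$nMetabolites, mean = 10, sd = 2), ids)
  })
  slopes <- setNames(rep(0, design$nMetabolites), ids)
  for (cl in names(trendSpec)) slopes[classes == cl] <- trendSpec[[cl]]

  planted <- list()
  tabs <- list()
  samples <- list()
  for (g in seq_len(nrow(groups))) {
    cv <- groups$cultivar[g]; st <- groups$stage[g]
    key <- keys[g]
    gseed <- groupSeed(design$seed, cv, st)
    spec <- specFor(key)
    pn <- if (identical(spec, "none")) {
      structure(list(group = c(cv, st), nodes = ids,
                     edges = data.frame(from = character(),
                                        to = character(),
                                        sign = numeric(),
                                        target_r = numeric()),
                     model = "hub", params = list()),
                class = "PlantedNetwork")
    } else if (identical(spec, "default")) {
      defaultPlanted(cv, st, gseed)
    } else if (inherits(spec, "PlantedNetwork")) {
      spec
    } else {
      makePlantedNetwork(c(cv, st), ids, spec$model,
                         spec$params %||% list(), seed = gseed)
    }
    planted[[key]] <- pn
    stageIdx <- match(st, design$stages) - 1L
    base <- baseline + slopes * stageIdx
    x <- sampleGroupMatrix(pn, nSamples = design$replicates,
                           noiseSd = noiseSd, seed = gseed,
                           baselineLog2 = base)
    perYear <- design$replicates / design$years
    yr <- rep(seq_len(design$years), each = perYear)
    sid <- sprintf("%s_%s_y%d_r%02d", cv, st, yr, seq_len(design$replicates))
    rownames(x) <- sid
    tabs[[key]] <- x
    samples[[key]] <- data.frame(sample_id = sid, cultivar = cv, stage = st,
                                 year = yr, stringsAsFactors = FALSE)
  }
  intensities <- do.call(rbind, tabs)
  samples <- do.call(rbind, samples)
  rownames(samples) <- NULL
  if (missingRate > 0) {
    intensities <- withSeed(groupSeed(design$seed, "missing"), {
      drop <- runif(length(intensities)) < missingRate
      intensities[drop] <- NA_real_
      intensities
    })
  }
  me <- MetaboliteExperiment(intensities, samples, metabolites,
                             stageOrder = design$stages)
  structure(list(experiment = me, planted = planted,
                 trendSpec = trendSpec, design = design),
            class = "SyntheticDataset")
}
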