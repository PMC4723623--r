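#' Benjamini--Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1 (thin wrapper over [stats::p.adjust()], kept as the single
#' correction entry point of the pipeline).
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return adjusted p-values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' One-way stage ANOVA with Tukey HSD follow-up for one metabolite
#'
#' Tests whether a metabolite's log2 level differs across developmental
#' stages within one cultivar. Tukey honest significant differences are
#' computed per stage pair only when the ANOVA p-value passes the gate;
#' untested pairs carry p = 1 by convention. Each pair also reports the
#' log2 median difference (later stage minus reference stage), the
#' fold-change proxy used downstream.
#'
#' @param me a log2 \linkS4class{MetaboliteExperiment}.
#' @param metabolite metabolite id.
#' @param cultivar cultivar label to subset.
#' @param gate ANOVA p-value gate for running Tukey (default 0.05).
#' @return data.frame, one row per stage pair: `metabolite`, `pair`
#'   (`"B-A"`, B later), `anova_p`, `p` (Tukey), `log2fc`.
#' @export
anovaTukey <- function(me, metabolite, cultivar, gate = 0.05) {
  stopifnot(processing(me) == "log2")
  x <- intensityMatrix(me, cultivar = cultivar)[, metabolite]
  cd <- SummarizedExperiment::colData(me)
  st <- cd$stage[cd$cultivar == cultivar]
  keep <- !is.na(x)
  x <- x[keep]; st <- st[keep]
  stages <- intersect(stageOrder(me), unique(st))
  cnt <- table(st)
  small <- names(cnt)[cnt < 2]
  if (length(stages) < 2) stop("need >= 2 stages with data")
  if (length(small)) {
    stop("group(s) with < 2 observations: ",
         paste(cultivar, small, sep = "/", collapse = ", "))
  }
  f <- factor(st, levels = stages)
  med <- tapply(x, f, median)
  pairs <- t(combn(stages, 2))
  pairLab <- paste(pairs[, 2], pairs[, 1], sep = "-")
  lfc <- med[pairs[, 2]] - med[pairs[, 1]]

  if (var(x) == 0) {
    ## all values identical: no evidence of any difference
    anova_p <- 1
    tk <- setNames(rep(1, length(pairLab)), pairLab)
  } else {
    fit <- aov(x ~ f)
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    if (is.na(anova_p)) anova_p <- 1
    if (anova_p < gate) {
      th <- TukeyHSD(fit)$f
      tk <- setNames(th[, "p adj"], rownames(th))
      tk <- tk[pairLab]
    } else {
      tk <- setNames(rep(1, length(pairLab)), pairLab)
    }
  }
  data.frame(metabolite = metabolite, pair = pairLab, anova_p = anova_p,
             p = unname(tk), log2fc = unname(lfc), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Stage-pair tests for all metabolites of one cultivar
#'
#' Runs [anovaTukey()] for every metabolite and appends BH-adjusted
#' p-values over the full (metabolite x stage pair) family of the
#' cultivar. Mode-specific counting in [significantChanges()] re-adjusts
#' within its own comparison family.
#'
#' @inheritParams anovaTukey
#' @return long data.frame: `cultivar`, `metabolite`, `pair`, `anova_p`,
#'   `p`, `p_adj`, `log2fc`.
#' @export
stageTests <- function(me, cultivar, gate = 0.05) {
  mets <- rownames(me)
  out <- do.call(rbind, lapply(mets, function(m) {
    anovaTukey(me, m, cultivar, gate = gate)
  }))
  out <- cbind(cultivar = cultivar, out, stringsAsFactors = FALSE)
  out$p_adj <- bhAdjust(out$p)
  out
}

#' Count significantly changing metabolites per stage
#'
#' A metabolite counts as up (down) at stage `s` when its BH-adjusted
#' stage-pair p-value is below `alpha` and its log2 median difference
#' against the reference stage is positive (negative). Reference is the
#' first stage (`vs_first`) or the immediately preceding stage
#' (`vs_previous`). BH is applied within the (mode x cultivar) family
#' across metabolites and the mode's stage pairs.
#'
#' @param tests output of [stageTests()].
#' @param mode `"vs_first"` or `"vs_previous"`.
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @param stages ordered stage labels (default the six berry stages).
#' @return data.frame: `cultivar`, `stage`, `mode`, `up`, `down`.
#' @export
significantChanges <- function(tests, mode = c("vs_first", "vs_previous"),
                               alpha = 0.05, stages = berryStages()) {
  mode <- match.arg(mode)
  ref <- if (mode == "vs_first") {
    data.frame(stage = stages[-1], ref = stages[1])
  } else {
    data.frame(stage = stages[-1], ref = stages[-length(stages)])
  }
  ref$pair <- paste(ref$stage, ref$ref, sep = "-")
  sub <- tests[tests$pair %in% ref$pair, , drop = FALSE]
  sub$p_mode_adj <- bhAdjust(sub$p)
  out <- do.call(rbind, lapply(seq_len(nrow(ref)), function(i) {
    rows <- sub[sub$pair == ref$pair[i], , drop = FALSE]
    sig <- !is.na(rows$p_mode_adj) & rows$p_mode_adj < alpha
    data.frame(cultivar = tests$cultivar[1], stage = ref$stage[i],
               mode = mode,
               up = sum(sig & rows$log2fc > 0),
               down = sum(sig & rows$log2fc < 0),
               stringsAsFactors = FALSE)
  }))
  ## the first stage compared with itself changes nothing by definition
  rbind(data.frame(cultivar = tests$cultivar[1], stage = stages[1],
                   mode = mode, up = 0L, down = 0L,
                   stringsAsFactors = FALSE),
        out)
}

#' Metabolites discriminating the two cultivars at one stage
#'
#' Welch two-sample test on log2 values per metabolite between the two
#' cultivars at the given stage, BH-corrected across metabolites, combined
#' with a twofold-change filter on the log2 median difference
#' (`|delta| >= minAbsLog2fc`).
#'
#' @param me a log2 \linkS4class{MetaboliteExperiment} containing exactly
#'   two cultivars.
#' @param stage stage label.
#' @param alpha significance level on adjusted p-values.
#' @param minAbsLog2fc twofold-change filter (default 1 log2 unit).
#' @return data.frame of discriminators: `metabolite`, `log2fc`
#'   (first cultivar minus second), `direction` (+1/-1), `p`, `p_adj`.
#' @export
cultivarDiscriminators <- function(me, stage, alpha = 0.05,
                                   minAbsLog2fc = 1) {
  stopifnot(processing(me) == "log2")
  cd <- SummarizedExperiment::colData(me)
  cvs <- unique(cd$cultivar)
  if (length(cvs) != 2) stop("need exactly two cultivars")
  xa <- intensityMatrix(me, cultivar = cvs[1], stage = stage)
  xb <- intensityMatrix(me, cultivar = cvs[2], stage = stage)
  if (!nrow(xa) || !nrow(xb)) stop("both cultivars must have samples at ", stage)
  res <- do.call(rbind, lapply(colnames(xa), function(m) {
    a <- xa[, m]; b <- xb[, m]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    lfc <- median(a) - median(b)
    p <- tryCatch(t.test(a, b)$p.value, error = function(e) {
      ## essentially constant data: call by the medians alone
      if (abs(lfc) > 0) 0 else 1
    })
    data.frame(metabolite = m, log2fc = lfc, p = p,
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- bhAdjust(res$p)
  res$direction <- sign(res$log2fc)
  keep <- !is.na(res$p_adj) & res$p_adj < alpha &
    abs(res$log2fc) >= minAbsLog2fc
  res[keep, c("metabolite", "log2fc", "direction", "p", "p_adj")]
}

#' Venn partition of two metabolite sets
#'
#' @param setA,setB character vectors.
#' @return list with counts `aOnly`, `bOnly`, `both` and the member
#'   vectors `membersAOnly`, `membersBOnly`, `membersBoth`.
#' @export
overlapSets <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  both <- intersect(setA, setB)
  list(aOnly = length(setdiff(setA, setB)),
       bOnly = length(setdiff(setB, setA)),
       both = length(both),
       membersAOnly = setdiff(setA, setB),
       membersBOnly = setdiff(setB, setA),
       membersBoth = both)
}

#' PCA of log2 metabolite levels
#'
#' Samples-by-metabolites PCA after centering and unit-variance scaling of
#' every metabolite. Missing entries are imputed at the column mean (zero
#' after standardization) and flagged; constant metabolites are set to
#' zero and flagged. Component orientation is fixed by forcing the
#' largest-magnitude loading of each component positive.
#'
#' @param me a log2 \linkS4class{MetaboliteExperiment}.
#' @param cultivar optional cultivar subset.
#' @param nComponents components to report in `scores`/`loadings`
#'   (explained-variance fractions cover all components).
#' @return list of class `"PCAResult"`: `scores`, `loadings`,
#'   `explained`, `imputed` (count), `constant` (metabolite ids).
#' @export
runPCA <- function(me, cultivar = NULL, nComponents = 2) {
  stopifnot(processing(me) == "log2")
  x <- intensityMatrix(me, cultivar = cultivar)
  if (nrow(x) < 2) stop("need >= 2 samples")
  mu <- colMeans(x, na.rm = TRUE)
  sdv <- apply(x, 2, sd, na.rm = TRUE)
  const <- colnames(x)[is.na(sdv) | sdv == 0]
  sdv[is.na(sdv) | sdv == 0] <- Inf
  z <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  nImp <- sum(is.na(z))
  z[is.na(z)] <- 0
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(nComponents, ncol(pc$rotation))
  rot <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores[, seq_len(k), drop = FALSE],
                 loadings = rot[, seq_len(k), drop = FALSE],
                 explained = expl,
                 fullScores = scores, fullLoadings = rot,
                 standardized = z,
                 imputed = nImp, constant = const),
            class = "PCAResult")
}

#' Hierarchical clustering of metabolite stage profiles
#'
#' Complete-linkage agglomerative clustering on Euclidean distances
#' between metabolite profiles (rows of the stage-median table). Rows are
#' sorted by id first so the result is deterministic regardless of input
#' order.
#'
#' @param profiles numeric matrix, metabolites by groups (e.g. from
#'   [stageMedians()]).
#' @return an [stats::hclust] tree with one leaf per metabolite.
#' @export
hcaTree <- function(profiles) {
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  hclust(dist(profiles, method = "euclidean"), method = "complete")
}

#' Serialize an HCA tree as Newick with merge heights as branch lengths
#'
#' @param tree an [stats::hclust] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
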