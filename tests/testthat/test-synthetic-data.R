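test_that("experiment design validates its invariants", {
  d <- experimentDesign()
  expect_equal(sum(d$classCounts), d$nMetabolites)
  expect_equal(d$nMetabolites, 115L)
  expect_error(experimentDesign(classCounts = c(sugar = 5), nMetabolites = 10),
               "class counts")
  expect_error(experimentDesign(replicates = 2), ">= 3")
  expect_error(experimentDesign(stages = c("FLW", "FLW")), "unique")
})

test_that("hub model plants a star when one hub owns every spoke", {
  nodes <- sprintf("m%02d", 1:10)
  pn <- makePlantedNetwork(c("CS", "FS"), nodes, "hub",
                           list(nHubs = 1, targetR = 0.9), seed = 5)
  expect_equal(nrow(pn$edges), 9)
  deg <- table(c(pn$edges$from, pn$edges$to))
  expect_equal(sort(as.integer(deg), decreasing = TRUE),
               c(9, rep(1, 9)))
  expect_false(any(pn$edges$from == pn$edges$to))
})

test_that("block model with two blocks of 5 gives 20 edges in 2 components", {
  nodes <- sprintf("m%02d", 1:10)
  pn <- makePlantedNetwork(c("CS", "FS"), nodes, "block",
                           list(blockSizes = c(5, 5), targetR = 0.8),
                           seed = 2)
  expect_equal(nrow(pn$edges), 2 * choose(5, 2))
  net <- metaboliteNetwork(nodes, as.matrix(pn$edges[, c("from", "to")]))
  sizes <- oracleComponents(adjacencyOf(net))
  expect_equal(sort(sizes[sizes >= 2]), c(5, 5))
})

test_that("random model edge counts follow the binomial oracle", {
  nodes <- sprintf("m%03d", 1:115)
  target <- 625
  p <- target / choose(115, 2)
  sdBin <- sqrt(choose(115, 2) * p * (1 - p))
  counts <- vapply(1:100, function(s) {
    nrow(makePlantedNetwork(c("CS", "FS"), nodes, "random",
                            list(nEdges = target), seed = s)$edges)
  }, numeric(1))
  expect_lt(abs(mean(counts) - target), 3 * sdBin / sqrt(100))
  expect_gte(mean(abs(counts - target) <= 3 * sdBin), 0.97)
})

test_that("invalid planting requests are rejected with a message", {
  nodes <- sprintf("m%02d", 1:10)
  expect_error(makePlantedNetwork(c("CS", "FS"), nodes, "smallworld"),
               "invalid model tag")
  expect_error(makePlantedNetwork(c("CS", "FS"), nodes, "random",
                                  list(nEdges = 100)), "pairs exist")
  expect_error(makePlantedNetwork(c("CS", "FS"), nodes[1:2], "hub"),
               "at least 3")
})

test_that("sampled matrices honor planted signs and near-deterministic edges", {
  nodes <- sprintf("m%02d", 1:5)
  pn <- makePlantedNetwork(c("CS", "FS"), nodes, "hub",
                           list(nHubs = 1, targetR = 0.999), seed = 1)
  x <- sampleGroupMatrix(pn, nSamples = 12, seed = 1)
  expect_true(all(x > 0))
  r <- spearmanMatrix(x)
  for (k in seq_len(nrow(pn$edges))) {
    expect_gt(r[pn$edges$from[k], pn$edges$to[k]] * pn$edges$sign[k], 0.95)
  }
  expect_error(sampleGroupMatrix(pn, 12, noiseSd = 0), "positive")
  expect_error(sampleGroupMatrix(pn, 2), ">= 3")
})

test_that("without planted edges the mean pairwise Spearman r is near zero", {
  nodes <- sprintf("m%02d", 1:5)
  pn <- makePlantedNetwork(c("CS", "FLW"), nodes, "random",
                           list(nEdges = 0), seed = 1)
  rs <- unlist(lapply(1:400, function(s) {
    x <- sampleGroupMatrix(pn, nSamples = 10, seed = s)
    r <- spearmanMatrix(x)
    r[upper.tri(r)]
  }))
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("a strong planted edge is realized near its target correlation", {
  nodes <- c("hub", "spoke", "other")
  pn <- makePlantedNetwork(c("CS", "FS"), nodes, "hub",
                           list(nHubs = 1, hubDegree = 2, targetR = 0.9),
                           seed = 3)
  obs <- vapply(1:300, function(s) {
    x <- sampleGroupMatrix(pn, nSamples = 10, seed = s)
    r <- spearmanMatrix(x)
    abs(r[pn$edges$from[1], pn$edges$to[1]])
  }, numeric(1))
  expect_gte(median(obs), 0.75)
})

test_that("the default design yields 120 samples by 115 metabolites", {
  ds <- generateExperiment(experimentDesign(seed = 9))
  expect_equal(dim(intensityMatrix(ds$experiment)), c(120L, 115L))
  expect_equal(length(ds$planted), 12L)
  ann <- metaboliteAnnotation(ds$experiment)
  expect_equal(as.vector(table(ann$class)[names(defaultClassCounts())]),
               unname(as.integer(defaultClassCounts())))
})

test_that("class-level log2 trends are recovered from stage medians", {
  cc <- c(sugar = 10L, `amino acid` = 10L)
  slopes <- c(sugar = 1, `amino acid` = -0.5)
  est <- vapply(1:20, function(s) {
    d <- experimentDesign(cultivars = "CS", replicates = 10, years = 2,
                          classCounts = cc, seed = s)
    ds <- generateExperiment(d, trendSpec = slopes, networkSpecs = "none")
    lg <- log2Transform(medianNormalize(ds$experiment))
    med <- stageMedians(lg)
    ann <- metaboliteAnnotation(lg)
    perMet <- apply(med, 1, function(y) coef(lm(y ~ seq_along(y)))[2])
    c(sugar = mean(perMet[ann$class == "sugar"]),
      amino = mean(perMet[ann$class == "amino acid"]))
  }, numeric(2))
  expect_lt(abs(mean(est["sugar", ]) - 1), 0.1)
  expect_lt(abs(mean(est["amino", ]) + 0.5), 0.1)
})

test_that("a null experiment keeps the raw ANOVA call rate at its nominal level", {
  rates <- vapply(42:44, function(s) {
    d <- experimentDesign(cultivars = "CS", replicates = 10, years = 2,
                          seed = s)
    ds <- generateExperiment(d, trendSpec = c(sugar = 0),
                             networkSpecs = "none")
    lg <- log2Transform(medianNormalize(ds$experiment))
    tests <- stageTests(lg, "CS", gate = 1)
    anovaP <- tapply(tests$anova_p, tests$metabolite, `[`, 1)
    mean(anovaP < 0.05)
  }, numeric(1))
  expect_lte(mean(rates), 0.07)
})

test_that("datasets round-trip through the TSV directory format", {
  d <- experimentDesign(cultivars = "CS", replicates = 4, years = 2,
                        classCounts = c(sugar = 4, acid = 4), seed = 11)
  ds <- generateExperiment(d, missingRate = 0.05)
  dir <- withr::local_tempdir()
  writeDataset(ds, dir)
  back <- readDataset(dir)
  expect_equal(intensityMatrix(back$experiment),
               intensityMatrix(ds$experiment))
  expect_equal(sampleAnnotation(back$experiment),
               sampleAnnotation(ds$experiment))
  expect_equal(metaboliteAnnotation(back$experiment),
               metaboliteAnnotation(ds$experiment))
  keyOf <- function(p) {
    paste(p$group[1], p$group[2], pmin(p$edges$from, p$edges$to),
          pmax(p$edges$from, p$edges$to), p$edges$sign)
  }
  expect_setequal(unname(unlist(lapply(back$planted, keyOf))),
                  unname(unlist(lapply(ds$planted, keyOf))))
})

test_that("malformed dataset directories fail loudly", {
  d <- experimentDesign(cultivars = "CS", replicates = 4, years = 2,
                        classCounts = c(sugar = 3), seed = 1)
  ds <- generateExperiment(d)
  dir <- withr::local_tempdir()
  writeDataset(ds, dir)
  samp <- read.delim(file.path(dir, "samples.tsv"))
  write.table(samp[, setdiff(names(samp), "cultivar")],
              file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(readDataset(dir), "cultivar")

  dir2 <- withr::local_tempdir()
  writeDataset(ds, dir2)
  writeLines("sample_id", file.path(dir2, "intensities.tsv"))
  expect_error(readDataset(dir2), "no metabolite data")
})

test_that("identical seeds reproduce the dataset exactly", {
  d <- experimentDesign(replicates = 4, years = 2,
                        classCounts = c(sugar = 5, acid = 5), seed = 21)
  a <- generateExperiment(d)
  b <- generateExperiment(d)
  expect_identical(intensityMatrix(a$experiment),
                   intensityMatrix(b$experiment))
  expect_identical(lapply(a$planted, `[[`, "edges"),
                   lapply(b$planted, `[[`, "edges"))
})
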