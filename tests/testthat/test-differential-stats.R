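test_that("BH adjustment matches the brute-force step-up procedure", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(bhAdjust(p), oracleBH(p))
  }
})

test_that("stage ANOVA handles degenerate and strong-signal inputs", {
  ## identical values everywhere: no difference, p = 1
  me <- toyExperiment(cbind(a = rep(3, 6)),
                      stage = rep(c("FLW", "FS"), each = 3),
                      processing = "log2")
  res <- anovaTukey(me, "a", "CS")
  expect_equal(res$anova_p, 1)
  expect_equal(res$p, 1)

  ## two well-separated groups: tiny p
  set.seed(1)
  me2 <- toyExperiment(cbind(a = c(rnorm(5, 0, 0.01), rnorm(5, 5, 0.01))),
                       stage = rep(c("FLW", "FS"), each = 5),
                       processing = "log2")
  res2 <- anovaTukey(me2, "a", "CS")
  expect_lt(res2$anova_p, 1e-6)
  expect_lt(res2$p, 1e-4)
  expect_equal(res2$pair, "FS-FLW")
  expect_gt(res2$log2fc, 4.5)

  ## a stage with a single observation is named in the error
  me3 <- toyExperiment(cbind(a = 1:4), stage = c("FLW", "FLW", "FLW", "FS"),
                       processing = "log2")
  expect_error(anovaTukey(me3, "a", "CS"), "CS/FS")
})

test_that("null ANOVA rejects at close to its nominal rate", {
  set.seed(99)
  hits <- vapply(1:400, function(i) {
    me <- toyExperiment(cbind(a = rnorm(15)),
                        stage = rep(c("FLW", "FS", "PRV"), each = 5),
                        processing = "log2")
    anovaTukey(me, "a", "CS", gate = 1)$anova_p[1] < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)
})

test_that("Tukey pairs are gated by the ANOVA p-value", {
  set.seed(2)
  me <- toyExperiment(cbind(a = rnorm(12)),
                      stage = rep(c("FLW", "FS", "PRV"), each = 4),
                      processing = "log2")
  res <- anovaTukey(me, "a", "CS", gate = 1e-12)
  expect_true(all(res$p == 1))  # gate not passed: untested pairs carry 1
})

test_that("change counting is faithful bookkeeping over stage pairs", {
  ## fabricate a test table: m1 significant up only in FS vs FLW
  stages <- berryStages()
  firstPairs <- paste(stages[-1], stages[1], sep = "-")
  prevPairs <- paste(stages[-1], stages[-6], sep = "-")
  pairs <- unique(c(firstPairs, prevPairs))
  tests <- expand.grid(metabolite = c("m1", "m2"), pair = pairs,
                       stringsAsFactors = FALSE)
  tests$cultivar <- "CS"
  tests$anova_p <- 0
  tests$p <- 1
  tests$log2fc <- 0
  hit <- tests$metabolite == "m1" & tests$pair == "FS-FLW"
  tests$p[hit] <- 1e-8
  tests$log2fc[hit] <- 2

  cf <- significantChanges(tests, "vs_first", alpha = 0.05)
  expect_equal(cf$up[cf$stage == "FLW"], 0L)   # first stage: zero by definition
  expect_equal(cf$up[cf$stage == "FS"], 1L)
  expect_equal(sum(cf$up) + sum(cf$down), 1)

  cp <- significantChanges(tests, "vs_previous", alpha = 0.05)
  expect_equal(cp$up[cp$stage == "FS"], 1L)
  expect_equal(sum(cp$up) + sum(cp$down), 1)  # appears exactly once

  ## nothing significant: all zero
  tests$p <- 1
  c0 <- significantChanges(tests, "vs_first")
  expect_true(all(c0$up == 0) && all(c0$down == 0))
})

test_that("a planted sugar trend is counted up at ripening vs flowering", {
  d <- experimentDesign(cultivars = "CS", replicates = 10, years = 2,
                        classCounts = c(sugar = 10, acid = 10), seed = 6)
  ds <- generateExperiment(d, trendSpec = c(sugar = 1),
                           networkSpecs = "none")
  lg <- log2Transform(medianNormalize(ds$experiment))
  tests <- stageTests(lg, "CS")
  cf <- significantChanges(tests, "vs_first")
  ann <- metaboliteAnnotation(lg)
  nSugar <- sum(ann$class == "sugar")
  expect_gte(cf$up[cf$stage == "RP"], ceiling(0.9 * nSugar))
})

test_that("cultivar discriminators respect both the test and the fold filter", {
  set.seed(10)
  base <- matrix(rnorm(20 * 6, sd = 0.1), 20, 6)
  vals <- rbind(base[1:10, ], base[11:20, ])
  ## m01 shifted +2 log2 in CS; m02 shifted +0.5 with tiny variance
  vals[1:10, 1] <- vals[1:10, 1] + 2
  vals[1:10, 2] <- vals[1:10, 2] + 0.5
  me <- toyExperiment(vals, stage = rep("VR", 20),
                      cultivar = rep(c("CS", "ME"), each = 10),
                      processing = "log2")
  disc <- cultivarDiscriminators(me, "VR")
  expect_true("m01" %in% disc$metabolite)
  expect_false("m02" %in% disc$metabolite)  # below twofold despite small p
  expect_equal(disc$direction[disc$metabolite == "m01"], 1)

  ## identical distributions: empty set
  me2 <- toyExperiment(rbind(base[1:10, ], base[1:10, ]),
                       stage = rep("VR", 20),
                       cultivar = rep(c("CS", "ME"), each = 10),
                       processing = "log2")
  expect_equal(nrow(cultivarDiscriminators(me2, "VR")), 0L)
})

test_that("set overlaps partition exactly", {
  expect_equal(overlapSets(c("a", "b"), c("a", "b"))[1:3],
               list(aOnly = 0L, bOnly = 0L, both = 2L))
  expect_equal(overlapSets(c("a", "b"), c("c"))[1:3],
               list(aOnly = 2L, bOnly = 1L, both = 0L))
  ov <- overlapSets(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(ov[1:3], list(aOnly = 1L, bOnly = 1L, both = 2L))
  expect_equal(ov$aOnly + ov$bOnly + ov$both,
               length(union(c("a", "b", "c"), c("b", "c", "d"))))
})

test_that("PCA captures perfect correlation, reconstructs, and fixes signs", {
  set.seed(3)
  v <- rnorm(10)
  me <- toyExperiment(cbind(a = v, b = 2 * v + 1), processing = "log2")
  pc <- runPCA(me)
  expect_equal(pc$explained[1], 1, tolerance = 1e-10)

  me2 <- toyExperiment(matrix(rnorm(12 * 7), 12, 7), processing = "log2")
  pc2 <- runPCA(me2, nComponents = 7)
  ## orthonormal loadings, exact reconstruction of the standardized data
  expect_equal(crossprod(pc2$fullLoadings), diag(7), tolerance = 1e-8,
               ignore_attr = TRUE)
  rec <- pc2$fullScores %*% t(pc2$fullLoadings)
  expect_lt(sqrt(sum((rec - pc2$standardized)^2)), 1e-8)
  ## orientation: largest-|loading| entry of each component positive
  for (j in 1:7) {
    expect_gt(pc2$fullLoadings[which.max(abs(pc2$fullLoadings[, j])), j], 0)
  }
})

test_that("isotropic noise gives no dominant component", {
  set.seed(5)
  me <- toyExperiment(matrix(rnorm(60 * 50), 60, 50), processing = "log2")
  pc <- runPCA(me)
  ## Marchenko-Pastur top-eigenvalue share for n=60, m=50 is about
  ## (1 + sqrt(50/60))^2 / 50 ~= 0.073; far from a structured 65%
  expect_lt(pc$explained[1], 0.15)
  expect_gt(pc$explained[1], 0.03)
})

test_that("PCA flags constant and missing metabolites", {
  v <- cbind(a = rnorm(8), b = rep(1, 8), c = rnorm(8))
  v[2, 3] <- NA
  me <- toyExperiment(v, processing = "log2")
  pc <- runPCA(me)
  expect_equal(pc$constant, "b")
  expect_equal(pc$imputed, 1L)
})

test_that("complete-linkage HCA follows hand computations", {
  prof <- rbind(a = c(0, 0), b = c(0, 0), c = c(3, 4))
  h <- hcaTree(prof)
  expect_equal(h$height[1], 0)           # identical profiles merge first
  prof2 <- rbind(a = 0, b = 1, c = 10)
  h2 <- hcaTree(prof2)
  expect_equal(h2$height, c(1, 10))      # complete linkage: final merge at 10
  expect_equal(length(h2$order), 3)
  f <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(h2, f)
  tr <- ape::read.tree(f)
  expect_setequal(tr$tip.label, c("a", "b", "c"))
})
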