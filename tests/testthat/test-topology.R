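test_that("a triangle plus an isolated node summarizes by hand", {
  net <- metaboliteNetwork(c("a", "b", "c", "d"),
                           cbind(c("a", "b", "c"), c("b", "c", "a")))
  s <- summarizeTopology(net)
  expect_equal(s$connected_nodes, 3L)
  expect_equal(s$isolated_nodes, 1L)
  expect_equal(s$edges, 3)
  expect_equal(s$connected_components, 1L)
  expect_equal(s$diameter, 1)
  expect_equal(s$average_path_length, 1)
  expect_equal(s$density, 3 / choose(4, 2))
  expect_equal(s$cluster_coefficient, 1)  # over connected nodes
  sU <- summarizeTopology(net, clusteringOver = "universe")
  expect_equal(sU$cluster_coefficient, 0.75)
})

test_that("an empty network reports zeros with the no-path flag", {
  net <- metaboliteNetwork(paste0("m", 1:5),
                           data.frame(from = character(), to = character()))
  s <- summarizeTopology(net)
  expect_equal(s$edges, 0)
  expect_equal(s$isolated_nodes, 5L)
  expect_equal(s$diameter, 0)
  expect_true(s$no_paths)
})

test_that("betweenness follows hand values on path, star and clique", {
  path <- metaboliteNetwork(c("a", "b", "c"),
                            cbind(c("a", "b"), c("b", "c")))
  b <- nodeBetweenness(path)
  expect_equal(b$betweenness, c(0, 1, 0))
  expect_equal(b$betweenness_normalized, c(0, 1, 0))

  k <- 6
  star <- metaboliteNetwork(c("hub", paste0("l", 1:k)),
                            cbind(rep("hub", k), paste0("l", 1:k)))
  bs <- nodeBetweenness(star)
  expect_equal(bs$betweenness[bs$node == "hub"], choose(k, 2))

  cl <- metaboliteNetwork(letters[1:5], t(combn(letters[1:5], 2)))
  expect_true(all(nodeBetweenness(cl)$betweenness == 0))
})

test_that("clustering coefficients match enumeration on the braced square", {
  ## square a-b-c-d-a braced by the diagonal a-c: the diagonal ends sit on
  ## two of their three neighbor pairs' triangles (Cn = 2/3), the side
  ## nodes on their only one (Cn = 1); confirmed by the enumeration oracle
  net <- metaboliteNetwork(c("a", "b", "c", "d"),
                           cbind(c("a", "b", "c", "d", "a"),
                                 c("b", "c", "d", "a", "c")))
  cn <- nodeClustering(net)
  expect_equal(unname(cn[c("a", "b", "c", "d")]), c(2/3, 1, 2/3, 1))
  expect_equal(unname(cn), unname(oracleClustering(adjacencyOf(net))))
  ## triangle node 1, star center 0
  tri <- metaboliteNetwork(c("a", "b", "c"),
                           cbind(c("a", "b", "c"), c("b", "c", "a")))
  expect_equal(unname(nodeClustering(tri)), rep(1, 3))
  star <- metaboliteNetwork(c("h", "x", "y"),
                            cbind(c("h", "h"), c("x", "y")))
  expect_equal(unname(nodeClustering(star)["h"]), 0)
})

test_that("all topology metrics agree with brute-force oracles on random graphs", {
  set.seed(12)
  for (i in 1:60) {
    n <- sample(4:25, 1)
    net <- randomToyNetwork(n, runif(1, 0.05, 0.5), seed = 1000 + i)
    A <- adjacencyOf(net)
    s <- summarizeTopology(net)
    ps <- oraclePathStats(A)
    sizes <- oracleComponents(A)
    expect_equal(s$diameter, ps$diameter)
    expect_equal(s$average_path_length, ps$apl)
    expect_equal(s$connected_components, sum(sizes >= 2))
    expect_equal(s$connected_nodes + s$isolated_nodes, n)
    expect_equal(s$density * choose(n, 2), s$edges)
    ct <- centralityTable(net)
    expect_equal(ct$degree, unname(rowSums(A)))
    expect_equal(ct$betweenness, oracleBetweenness(A), tolerance = 1e-9)
    expect_equal(ct$clustering, unname(oracleClustering(A)))
  }
})

test_that("dropping an isolated node only rescales density", {
  net <- metaboliteNetwork(c("a", "b", "c", "d", "iso"),
                           cbind(c("a", "b", "c"), c("b", "c", "d")))
  sub <- metaboliteNetwork(c("a", "b", "c", "d"),
                           cbind(c("a", "b", "c"), c("b", "c", "d")))
  sFull <- summarizeTopology(net)
  sSub <- summarizeTopology(sub)
  expect_equal(sFull$edges, sSub$edges)
  expect_gt(sSub$density, sFull$density)
  cFull <- centralityTable(net); cSub <- centralityTable(sub)
  shared <- cSub$node
  expect_equal(cFull$betweenness[match(shared, cFull$node)],
               cSub$betweenness)
  expect_equal(cFull$clustering[match(shared, cFull$node)],
               cSub$clustering)
})

test_that("degree-distribution fitting selects the generating family", {
  ## fewer than 5 distinct degrees: flagged unfit-able
  expect_false(fitDegreeDistribution(c(1L, 1L, 2L, 2L))$fitable)

  ## power-law degrees favor the power-law CCDF model
  set.seed(3)
  kmax <- 60
  pk <- (1:kmax)^-2
  hits <- vapply(1:25, function(s) {
    set.seed(s)
    deg <- sample(1:kmax, 115, replace = TRUE, prob = pk)
    fitDegreeDistribution(deg)$selected == "power_law"
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  ## Poisson random-graph degrees favor the exponential CCDF model
  hitsP <- vapply(1:25, function(s) {
    set.seed(s)
    deg <- rpois(115, 4)
    fitDegreeDistribution(deg)$selected == "exponential"
  }, logical(1))
  expect_gte(mean(hitsP), 0.8)
})

test_that("AIC bookkeeping is internally consistent", {
  set.seed(9)
  deg <- sample(1:40, 115, replace = TRUE, prob = (1:40)^-2)
  fit <- fitDegreeDistribution(deg)
  expect_true(fit$fitable)
  aics <- c(fit$fits$power_law$aic, fit$fits$exponential$aic)
  expect_equal(fit$selected,
               c("power_law", "exponential")[which.min(aics)])
  expect_equal(sum(fit$akaike_weights), 1)
  expect_equal(min(fit$delta_aic), 0)
})
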