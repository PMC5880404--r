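test_that("two-point estimates match closed forms", {
  a <- rep(c("a", "b"), 50)
  pr <- pairwiseRf(a, a)
  expect_equal(pr$rhat, 0)
  expect_identical(pr$phase, "coupling")
  expect_equal(pr$lod, 100 * log10(2), tolerance = 1e-12)
  expect_equal(pr$lod, 30.103, tolerance = 1e-4)
  # complementary columns: r = 0 in repulsion
  b <- ifelse(a == "a", "b", "a")
  pr <- pairwiseRf(a, b)
  expect_equal(pr$rhat, 0)
  expect_identical(pr$phase, "repulsion")
  # 5 recombinants among 213 complete pairs
  x <- rep("a", 213)
  y <- x; y[1:5] <- "b"
  pr <- pairwiseRf(x, y)
  expect_equal(round(pr$rhat, 3), 0.023)
  expect_identical(pr$nInformative, 213L)
  expect_error(pairwiseRf(rep(NA_character_, 5), rep("a", 5)),
               "no information")
  expect_true(pairwiseRf(rep(c("a", "b"), 5), rep("a", 10))$lowConfidence)
})

test_that("the rf matrix equals the brute-force pair loop", {
  set.seed(101)
  cl <- matrix(sample(c("a", "b", NA), 30 * 25, replace = TRUE,
                      prob = c(0.45, 0.45, 0.1)), nrow = 30)
  rownames(cl) <- sprintf("m%02d", 1:30)
  colnames(cl) <- sprintf("i%02d", 1:25)
  rf <- pairwiseRfMatrix(cl)
  worstR <- worstLod <- 0; nOk <- couplingOk <- TRUE
  for (i in 1:29) for (j in (i + 1):30) {
    pr <- pairwiseRf(cl[i, ], cl[j, ])
    worstR <- max(worstR, abs(rf$r[i, j] - pr$rhat))
    worstLod <- max(worstLod, abs(rf$lod[i, j] - pr$lod))
    nOk <- nOk && rf$n[i, j] == pr$nInformative
    couplingOk <- couplingOk &&
      rf$coupling[i, j] == (pr$phase == "coupling")
  }
  expect_lt(worstR, 1e-12)
  expect_lt(worstLod, 1e-10)
  expect_true(nOk)
  expect_true(couplingOk)
  # symmetry
  expect_equal(rf$r, t(rf$r))
  expect_equal(rf$lod, t(rf$lod))
})

test_that("LOD grouping is transitive and monotone in the threshold", {
  pop <- simulatePopulation(tinyConfig(n = 213, spacing = 5, seed = 55))
  xf <- pop$genotypes[
    markerInfo(pop$genotypes)$segregatingParent == "female", ]
  rf <- pairwiseRfMatrix(xf)
  g12 <- groupMarkers(rf, 12, 0.4)
  expect_length(g12[lengths(g12) >= 2], 2)
  tm <- pop$truth$femaleMap
  for (g in g12[lengths(g12) >= 2])
    expect_length(unique(tm$chromosome[match(g, tm$marker)]), 1)
  # a huge threshold isolates every marker
  gAll <- groupMarkers(rf, 1e6, 0.4)
  expect_true(all(lengths(gAll) == 1))
  # refinement: every group at LOD 12 lies inside one group at LOD 4
  g4 <- groupMarkers(rf, 4, 0.4)
  whichG4 <- function(m) which(vapply(g4, function(g) m %in% g,
                                      logical(1)))
  for (g in g12)
    expect_length(unique(vapply(g, whichG4, integer(1))), 1)
})

test_that("map functions match closed forms and each other", {
  expect_equal(kosambiCm(0), 0)
  expect_equal(kosambiCm(0.1), 10.14, tolerance = 5e-3)
  expect_equal(kosambiCm(0.25), 27.47, tolerance = 5e-3)
  expect_error(kosambiCm(0.5), "0.5")
  expect_error(kosambiCm(-0.01), "0.5")
  expect_error(haldaneCm(0.5))
  r <- seq(0.01, 0.49, by = 0.01)
  expect_true(all(diff(kosambiCm(r)) > 0))
  expect_true(all(kosambiCm(r) <= haldaneCm(r)))
  expect_equal(haldaneR(haldaneCm(r)), r, tolerance = 1e-12)
})

test_that("three-marker ordering picks the SARF-minimal chain", {
  r <- matrix(c(0, 0.05, 0.10,
                0.05, 0, 0.05,
                0.10, 0.05, 0), 3, 3,
              dimnames = list(c("m1", "m2", "m3"), c("m1", "m2", "m3")))
  res <- orderGroup(c("m1", "m2", "m3"), list(r = r))
  expect_identical(res$order, c("m1", "m2", "m3"))
  expect_equal(res$sarf, 0.10)
  # two markers: canonical orientation, SARF = r
  res2 <- orderGroup(c("mB", "mA"), list(r = matrix(
    c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("mB", "mA"),
                                             c("mB", "mA")))))
  expect_identical(res2$order, c("mA", "mB"))
  expect_equal(res2$sarf, 0.2)
})

test_that("2-opt ordering matches brute force on six markers", {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  allOrders <- perms(1:6)
  hits <- 0
  nrep <- 60
  for (sd in seq_len(nrep)) {
    set.seed(sd)
    pos <- sort(runif(6, 0, 60))
    # simulate 200 backcross haplotypes along the chromosome
    n <- 200
    z <- matrix(0L, 6, n)
    z[1, ] <- sample(0:1, n, replace = TRUE)
    for (k in 2:6) {
      rk <- haldaneR(pos[k] - pos[k - 1])
      flip <- runif(n) < rk
      z[k, ] <- ifelse(flip, 1L - z[k - 1, ], z[k - 1, ])
    }
    cl <- matrix(c("a", "b")[z + 1], 6, n,
                 dimnames = list(paste0("m", 1:6), paste0("i", 1:n)))
    rf <- pairwiseRfMatrix(cl)
    best <- min(vapply(allOrders, function(o)
      sum(rf$r[cbind(o[-6], o[-1])]), numeric(1)))
    got <- orderGroup(rownames(cl), rf)$sarf
    if (abs(got - best) < 1e-12) hits <- hits + 1
  }
  expect_gte(hits / nrep, 0.95)
})

test_that("map construction reproduces the summary arithmetic", {
  # 205 markers spanning 99.1 cM: density 0.5
  k <- 205
  tb <- data.frame(group = "G1", marker = sprintf("m%03d", 1:k),
                   position = seq(0, 99.1, length.out = k),
                   asterisks = "")
  s <- mapSummary(GeneticMap(tb))
  expect_equal(s$size, 99.1)
  expect_equal(s$density, 0.5)
  expect_identical(s$gaps, 0L)
  # a single 6-cM interval is one gap
  tb2 <- data.frame(group = "G1", marker = c("a", "b", "c"),
                    position = c(0, 6, 8), asterisks = "")
  expect_identical(mapSummary(GeneticMap(tb2))$gaps, 1L)
  # 11 markers with adjacent r = 0.0198 span 10 x kosambi(0.0198)
  ids <- sprintf("k%02d", 1:11)
  r <- matrix(0.4, 11, 11, dimnames = list(ids, ids))
  r[cbind(1:10, 2:11)] <- r[cbind(2:11, 1:10)] <- 0.0198
  diag(r) <- 0
  coup <- matrix(TRUE, 11, 11, dimnames = list(ids, ids))
  mp <- buildMap(list(G1 = ids), list(r = r, coupling = coup))
  expect_equal(max(mapTable(mp)$position), 10 * kosambiCm(0.0198),
               tolerance = 1e-9)
  expect_equal(round(max(mapTable(mp)$position), 1), 19.8)
  # single-marker group: size 0 with a warning
  mp1 <- buildMap(list(G1 = ids, G2 = "solo"),
                  list(r = r, coupling = coup))
  expect_warning(s1 <- mapSummary(mp1), "single-marker")
  expect_equal(s1$size[2], 0)
})

test_that("simulated chromosomes are recovered to length within 15%", {
  pop <- simulatePopulation(
    simConfig(213, list(list(name = "c1", armLeft = 50, armRight = 50,
                             markerPositions = 0:100)),
              seed = 99))
  xf <- pop$genotypes[
    markerInfo(pop$genotypes)$segregatingParent == "female", ]
  pm <- buildParentMap(xf, 12, 0.4)
  s <- mapSummary(pm$map)
  expect_length(unique(mapTable(pm$map)$group), 1)
  expect_lt(abs(s$size[1] - 100) / 100, 0.15)
})

test_that("association LOD is margin-conditioned", {
  # two independent but equally distorted markers: association ~ 0,
  # while the testcross LOD would spuriously indicate linkage
  set.seed(5)
  n <- 200
  a <- sample(c("a", "b"), n, replace = TRUE, prob = c(0.9, 0.1))
  b <- sample(c("a", "b"), n, replace = TRUE, prob = c(0.9, 0.1))
  cl <- rbind(m1 = a, m2 = b)
  colnames(cl) <- paste0("i", 1:n)
  assoc <- pairwiseAssociationLod(cl)
  expect_lt(assoc[1, 2], 2)
  expect_gt(pairwiseRfMatrix(cl)$lod[1, 2], 4)
  # oracle: the G-statistic of the 2x2 table, computed directly
  tab <- table(a, b)
  e <- outer(rowSums(tab), colSums(tab)) / n
  g2 <- 2 * sum(ifelse(tab > 0, tab * log(tab / e), 0))
  expect_equal(assoc[1, 2], g2 / (2 * log(10)), tolerance = 1e-10)
  # perfectly associated markers score high
  cl2 <- rbind(m1 = a, m2 = a)
  colnames(cl2) <- paste0("i", 1:n)
  expect_gt(pairwiseAssociationLod(cl2)[1, 2], 10)
})
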