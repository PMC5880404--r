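test_that("phenotype summaries use the adjusted moment conventions", {
  # the N-only standard errors at the study population size
  s <- summarizePhenotype(rnorm(213))
  expect_equal(round(s$seSkewness, 3), 0.167)
  expect_equal(round(s$seKurtosis, 3), 0.332)
  # perfectly symmetric sample has zero skewness
  v <- c(1:9, 9:1)
  expect_equal(summarizePhenotype(v)$skewness, 0, tolerance = 1e-12)
  # adjusted Fisher-Pearson moments match the e1071 type-2 oracle
  set.seed(30)
  v <- rnorm(30)^2
  s <- summarizePhenotype(v)
  expect_equal(s$skewness, e1071::skewness(v, type = 2),
               tolerance = 1e-10)
  expect_equal(s$kurtosis, e1071::kurtosis(v, type = 2),
               tolerance = 1e-10)
  expect_equal(s$seMean, sd(v) / sqrt(30), tolerance = 1e-12)
  expect_error(summarizePhenotype(c(1, 2, 3)), "at least 4")
})

test_that("Kruskal-Wallis matches hand-ranked and tie-corrected oracles", {
  tv <- setNames(c(1, 2, 3, 4, 5, 6), paste0("i", 1:6))
  mk <- c("a", "a", "a", "b", "b", "b")
  kw <- kruskalWallisMarker(tv, mk)
  expect_equal(round(kw$H, 3), 3.857)
  expect_identical(kw$df, 1L)
  # heavy ties: tie-corrected H computed from the closed formula
  tv2 <- setNames(c(1, 1, 2, 2, 2, 3, 3, 1, 2, 3), paste0("j", 1:10))
  mk2 <- rep(c("a", "b"), each = 5)
  kw2 <- kruskalWallisMarker(tv2, mk2)
  rk <- rank(tv2)
  n <- 10
  Rj <- tapply(rk, mk2, sum)
  nj <- tapply(rk, mk2, length)
  Hraw <- 12 / (n * (n + 1)) * sum(Rj^2 / nj) - 3 * (n + 1)
  ties <- table(tv2)
  Hties <- Hraw / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(kw2$H, unname(Hties), tolerance = 1e-10)
  # null calibration over replicates
  set.seed(77)
  ps <- replicate(200, {
    y <- setNames(rnorm(40), paste0("k", 1:40))
    g <- rep(c("a", "b"), 20)
    kruskalWallisMarker(y, g)$p
  })
  expect_lt(abs(mean(ps) - 0.5), 0.08)
  expect_error(kruskalWallisMarker(tv, rep("a", 6)), "2 genotype")
})

test_that("interval mapping matches closed forms at markers", {
  # constant trait: zero LOD everywhere
  pop <- simulatePopulation(tinyConfig(n = 80, spacing = 10, seed = 3))
  xf <- pop$genotypes[
    markerInfo(pop$genotypes)$segregatingParent == "female", ]
  mp <- GeneticMap(data.frame(
    group = pop$truth$femaleMap$chromosome,
    marker = pop$truth$femaleMap$marker,
    position = pop$truth$femaleMap$cm, asterisks = ""))
  tvConst <- setNames(rep(5, 80), individuals(xf))
  prof <- intervalMapping(mp, xf, tvConst)
  expect_true(all(abs(prof$lod) < 1e-10))
  # QTL at a fully informative marker with R^2 = 0.3, n = 200:
  # lod = -100 log10(0.7) = 15.49
  set.seed(9)
  n <- 200
  z <- sample(c(1, -1), n, replace = TRUE)
  e <- rnorm(n)
  e <- residuals(lm(e ~ z))                   # exactly orthogonal noise
  e <- e / sd(e)
  b <- sqrt(0.3 / 0.7) * sd(z) / sd(z)        # scale for R^2 = 0.3
  y <- b * z / sd(z) * sqrt(var(z)) + e
  y <- z * sqrt(0.3 / 0.7 * var(e) / var(z)) + e
  r2 <- summary(lm(y ~ z))$r.squared
  expect_equal(r2, 0.3, tolerance = 1e-10)
  cl <- rbind(m1 = ifelse(z == 1, "a", "b"),
              m2 = ifelse(z == 1, "a", "b"))
  colnames(cl) <- paste0("i", 1:n)
  info <- data.frame(scaffold = c("s1", "s2"), position = c(1L, 2L),
                     snpType = "IV", segregatingParent = "female",
                     row.names = c("m1", "m2"))
  xg <- TestcrossGenotypes(cl, info)
  mp2 <- GeneticMap(data.frame(group = "G1", marker = c("m1", "m2"),
                               position = c(0, 10), asterisks = ""))
  tv <- setNames(y, colnames(cl))
  prof2 <- intervalMapping(mp2, xg, tv)
  atM <- prof2[prof2$position == 0, ]
  expect_equal(atM$lod, -100 * log10(0.7), tolerance = 1e-8)
  expect_equal(atM$lod, 15.49, tolerance = 1e-2)
  expect_equal(atM$pv, 0.3, tolerance = 1e-10)
})

test_that("interval mapping reduces to marker regression at markers", {
  pop <- simulatePopulation(tinyConfig(
    n = 150, spacing = 10, seed = 21,
    qtls = data.frame(parent = "female", chromosome = "chrA",
                      position = 25, additive = 0.8)))
  tm <- pop$truth$femaleMap
  mp <- GeneticMap(data.frame(group = tm$chromosome, marker = tm$marker,
                              position = tm$cm, asterisks = ""))
  xf <- pop$genotypes[tm$marker, ]
  tv <- setNames(pop$traits$trait, pop$traits$individual)
  prof <- intervalMapping(mp, xf, tv)
  cl <- calls(xf)
  for (k in seq_len(nrow(tm))) {
    z <- ifelse(cl[tm$marker[k], ] == "a", 1, -1)
    r2 <- summary(lm(tv ~ z))$r.squared
    lodMarker <- -(150 / 2) * log10(1 - r2)
    got <- prof$lod[prof$group == tm$chromosome[k] &
                      prof$position == tm$cm[k]]
    expect_equal(got, lodMarker, tolerance = 1e-8)
  }
  # pv is invariant to affine trait transforms; additive scales
  prof2 <- intervalMapping(mp, xf, 3 * tv + 7)
  expect_equal(prof2$pv, prof$pv, tolerance = 1e-10)
  expect_equal(abs(prof2$additive), 3 * abs(prof$additive),
               tolerance = 1e-10)
  expect_equal(prof2$lod, prof$lod, tolerance = 1e-10)
})

test_that("cofactor backward elimination keeps true signals", {
  keptNoise <- keptQtl <- keptBoth <- 0
  for (sd in 1:10) {
    pop <- simulatePopulation(tinyConfig(
      n = 150, spacing = 10, seed = 400 + sd,
      qtls = data.frame(parent = "female",
                        chromosome = c("chrA", "chrB"),
                        position = c(20, 20),
                        additive = c(0.9, 0.9)),
      residualSd = 1))
    tm <- pop$truth$femaleMap
    xf <- pop$genotypes[tm$marker, ]
    tv <- setNames(pop$traits$trait, pop$traits$individual)
    candA <- tm$marker[tm$chromosome == "chrA" & tm$cm == 20]
    candB <- tm$marker[tm$chromosome == "chrB" & tm$cm == 20]
    kept <- selectCofactors(xf, tv, c(candA, candB))$marker
    if (candA %in% kept) keptQtl <- keptQtl + 1
    if (all(c(candA, candB) %in% kept)) keptBoth <- keptBoth + 1
    # pure-noise trait: how often any candidate survives
    keptN <- selectCofactors(xf, setNames(sample(unname(tv)), names(tv)),
                             c(candA, candB))$marker
    if (length(keptN) == 0) keptNoise <- keptNoise + 1
  }
  expect_gte(keptQtl, 9)       # strong QTL retained in >= 90% of seeds
  expect_gte(keptBoth, 8)      # both unlinked QTL in >= 80%
  expect_gte(keptNoise, 8)     # noise candidates eliminated
  # collinear candidates: the later-entered duplicate is removed
  cl <- calls(xf)[c(candA, candB), ]
  cl <- rbind(cl, dup = cl[1, ])
  info <- data.frame(scaffold = c("s1", "s2", "s3"),
                     position = 1:3, snpType = "IV",
                     segregatingParent = "female",
                     row.names = rownames(cl))
  xd <- TestcrossGenotypes(cl, info)
  tv2 <- setNames(rnorm(ncol(cl)) + 2 * (cl[1, ] == "a"),
                  colnames(cl))
  expect_message(
    kept <- selectCofactors(xd, tv2, rownames(cl))$marker,
    "aliased cofactor dup")
  expect_false("dup" %in% kept)
})

test_that("MQM equals SIM without cofactors and absorbs background", {
  pop <- simulatePopulation(tinyConfig(
    n = 150, spacing = 10, seed = 31,
    qtls = data.frame(parent = "female",
                      chromosome = c("chrA", "chrB"),
                      position = c(20, 20), additive = c(0.7, 0.7))))
  tm <- pop$truth$femaleMap
  mp <- GeneticMap(data.frame(group = tm$chromosome, marker = tm$marker,
                              position = tm$cm, asterisks = ""))
  xf <- pop$genotypes[tm$marker, ]
  tv <- setNames(pop$traits$trait, pop$traits$individual)
  sim <- intervalMapping(mp, xf, tv)
  mqm0 <- mqmScan(mp, xf, tv, character())
  expect_equal(mqm0$lod, sim$lod, tolerance = 1e-10)
  expect_equal(mqm0$pv, sim$pv, tolerance = 1e-10)
  # a cofactor on the other group absorbs its QTL variance: LOD at the
  # scanned QTL should not drop, typically rises
  cofB <- tm$marker[tm$chromosome == "chrB" & tm$cm == 20]
  mqm <- mqmScan(mp, xf, tv, cofB)
  atA <- sim$group == "chrA" & sim$position == 20
  expect_gte(mqm$lod[atA], sim$lod[atA] - 0.2)
  # a cofactor on the scanned group near the test position is excluded
  # (the profile is not driven to zero by self-fitting)
  cofA <- tm$marker[tm$chromosome == "chrA" & tm$cm == 20]
  mqmSelf <- mqmScan(mp, xf, tv, cofA, exclusionWindow = 20)
  expect_gt(mqmSelf$lod[atA], 1)
  expect_equal(mqmSelf$lod[atA], sim$lod[atA], tolerance = 1e-10)
})

test_that("permutation thresholds are reproducible and calibrated", {
  pop <- simulatePopulation(tinyConfig(n = 100, spacing = 10, seed = 41))
  tm <- pop$truth$femaleMap
  mp <- GeneticMap(data.frame(group = tm$chromosome, marker = tm$marker,
                              position = tm$cm, asterisks = ""))
  xf <- pop$genotypes[tm$marker, ]
  tv <- setNames(pop$traits$trait, pop$traits$individual)
  p1 <- permutationThreshold(mp, xf, tv, nPerm = 150, seed = 7)
  p2 <- permutationThreshold(mp, xf, tv, nPerm = 150, seed = 7)
  expect_identical(p1$threshold, p2$threshold)
  expect_length(p1$maxLods, 150)
  expect_error(permutationThreshold(mp, xf, tv, nPerm = 50), "at least")
})

test_that("genome-wide thresholds fall in the study band", {
  # 11 groups of ~100 markers, n = 213: thresholds between 2.5 and 3.6
  thr <- vapply(1:4, function(sd) {
    pop <- simulatePopulation(
      translocationStudyConfig(213, 1, translocation = FALSE,
                               seed = 600 + sd, residualSd = 1))
    tm <- pop$truth$femaleMap
    mp <- GeneticMap(data.frame(group = tm$chromosome,
                                marker = tm$marker,
                                position = tm$cm, asterisks = ""))
    xf <- pop$genotypes[tm$marker, ]
    tv <- setNames(pop$traits$trait, pop$traits$individual)
    permutationThreshold(mp, xf, tv, nPerm = 200, seed = sd)$threshold
  }, numeric(1))
  expect_true(all(thr > 2.5 & thr < 3.6))
})

test_that("QTL calls follow the peak and dip rules", {
  prof <- data.frame(
    group = "G1", position = 0:20,
    lod = c(0.5, 1, 2, 4, 6, 5.2, 4.8, 5.5, 5.8, 4.5, 3.0,
            2.2, 3.5, 6.5, 7.2, 6.4, 4.0, 2.0, 1.0, 0.5, 0.2),
    pv = 0.1, additive = 0.5,
    nearestMarker = sprintf("m%02d", 0:20))
  # everything below an absurd threshold: no calls
  expect_identical(nrow(callQtls(prof, 100, "F")), 0L)
  # twin peaks at 4/8 merge (dip 6 - 4.8 = 1.2 from the lower peak 5.8?
  # no: dip measured from the lower of the two peaks: min(6, 5.8) -
  # 4.8 = 1.0, not > 1, so they merge; the 14-peak is separated by the
  # 2.2 valley (dip 3.7 > 1)
  calls <- callQtls(prof, 3.1, "F", year = 2013)
  expect_identical(nrow(calls), 2L)
  expect_setequal(calls$peakCm, c(4, 14))
  expect_true(all(calls$lod >= 3.1))
  expect_identical(calls$name[1], "lb_F_G1_13")
  # 1-LOD support interval contains the peak and respects the drop
  c14 <- calls[calls$peakCm == 14, ]
  expect_true(c14$intervalLo <= 14 && c14$intervalHi >= 14)
  expect_equal(c(c14$intervalLo, c14$intervalHi), c(13, 15))
  # twin peaks with an intervening dip > 1 stay separate calls
  prof2 <- data.frame(group = "G1", position = 0:6,
                      lod = c(0, 5, 3.4, 5, 0.5, 0.2, 0),
                      pv = 0.1, additive = 1,
                      nearestMarker = paste0("n", 0:6))
  expect_identical(nrow(callQtls(prof2, 3.1, "F")), 2L)
})
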