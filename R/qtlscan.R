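#' Phenotype summary with moment standard errors
#'
#' Mean, SD, range, SE of the mean, adjusted Fisher-Pearson skewness and
#' excess kurtosis (the convention of mainstream statistics suites),
#' with their N-only standard errors:
#' `SE_skew = sqrt(6 N (N-1) / ((N-2)(N+1)(N+3)))` and
#' `SE_kurt = sqrt(4 (N^2 - 1) SE_skew^2 / ((N-3)(N+5)))`.
#'
#' @param values numeric trait values (NA dropped; at least 4 required).
#' @return list with `n`, `mean`, `sd`, `range`, `seMean`, `skewness`,
#'   `seSkewness`, `kurtosis`, `seKurtosis`.
#' @examples
#' summarizePhenotype(rnorm(213))$seSkewness  # 0.167 for N = 213
#' @export
summarizePhenotype <- function(values) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n < 4) stop("undefined moments: need at least 4 observations")
  m <- mean(v)
  m2 <- mean((v - m)^2); m3 <- mean((v - m)^3); m4 <- mean((v - m)^4)
  g1 <- if (m2 > 0) m3 / m2^1.5 else 0
  g2 <- if (m2 > 0) m4 / m2^2 - 3 else 0
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  G2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  seSkew <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  seKurt <- sqrt(4 * (n^2 - 1) * seSkew^2 / ((n - 3) * (n + 5)))
  list(n = n, mean = m, sd = stats::sd(v), range = range(v),
       seMean = stats::sd(v) / sqrt(n),
       skewness = G1, seSkewness = seSkew,
       kurtosis = G2, seKurtosis = seKurt)
}

#' Kruskal-Wallis marker-trait association
#'
#' Rank-based H statistic with tie correction (via [stats::kruskal.test])
#' between a trait and the genotype classes of one marker; classes that
#' are empty after missing-data removal are dropped with a message.
#'
#' @param trait named numeric vector (names = individual ids).
#' @param markerCalls character calls for one marker, same individuals.
#' @return list with `H`, `df`, `p`, `classSizes`.
#' @export
kruskalWallisMarker <- function(trait, markerCalls) {
  ok <- !is.na(trait) & !is.na(markerCalls)
  g <- factor(markerCalls[ok])
  if (nlevels(g) < length(unique(stats::na.omit(markerCalls))))
    message("kruskalWallisMarker: empty class dropped")
  if (nlevels(g) < 2)
    stop("need at least 2 genotype classes")
  if (any(table(g) < 2))
    stop("each genotype class needs at least 2 members")
  kt <- stats::kruskal.test(trait[ok], g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, classSizes = as.integer(table(g)))
}

# +1/-1/NA coding of testcross calls
.zCode <- function(cl) {
  z <- matrix(NA_real_, nrow(cl), ncol(cl), dimnames = dimnames(cl))
  z[cl == "a"] <- 1; z[cl == "b"] <- -1
  z
}

# expected QTL code E[z | flanking markers] on a cM grid for one linkage
# group, via Haldane transition probabilities (single recombination event
# modelled within each interval); missing flanks degrade to single-marker
# conditioning, both missing to 0
.expectedCodeGrid <- function(positions, z, step) {
  size <- max(positions)
  grid <- sort(unique(c(seq(0, size, by = step), positions)))
  nInd <- ncol(z)
  X <- matrix(0, length(grid), nInd)
  li <- findInterval(grid, positions)            # last marker <= p
  ri <- length(positions) + 1L - findInterval(-grid, rev(-positions))
  for (k in seq_along(grid)) {
    p <- grid[k]
    L <- li[k]; R <- ri[k]
    zL <- if (L >= 1) z[L, ] else rep(NA_real_, nInd)
    zR <- if (R <= length(positions)) z[R, ] else rep(NA_real_, nInd)
    rL <- if (L >= 1) haldaneR(p - positions[L]) else NA
    rR <- if (R <= length(positions)) haldaneR(positions[R] - p) else NA
    bothOk <- !is.na(zL) & !is.na(zR)
    onlyL <- !is.na(zL) & is.na(zR)
    onlyR <- is.na(zL) & !is.na(zR)
    e <- numeric(nInd)
    if (any(bothOk)) {
      fL <- ifelse(zL[bothOk] == 1, 1 - rL, rL)    # P(L obs | Q = +1)
      fR <- ifelse(zR[bothOk] == 1, 1 - rR, rR)
      gL <- ifelse(zL[bothOk] == 1, rL, 1 - rL)    # P(L obs | Q = -1)
      gR <- ifelse(zR[bothOk] == 1, rR, 1 - rR)
      e[bothOk] <- (fL * fR - gL * gR) / (fL * fR + gL * gR)
    }
    if (any(onlyL)) e[onlyL] <- zL[onlyL] * (1 - 2 * rL)
    if (any(onlyR)) e[onlyR] <- zR[onlyR] * (1 - 2 * rR)
    X[k, ] <- e
  }
  nearest <- vapply(grid, function(p)
    which.min(abs(positions - p)), integer(1))
  list(grid = grid, X = X, nearest = nearest)
}

# per-group expected-code grids for a map and genotype set
.scanDesign <- function(map, x, step) {
  tb <- mapTable(map)
  cl <- calls(x)
  lapply(split(tb, factor(tb$group, levels = unique(tb$group))),
         function(g) {
           ids <- g$marker[g$marker %in% rownames(cl)]
           g <- g[g$marker %in% ids, , drop = FALSE]
           z <- .zCode(cl[g$marker, , drop = FALSE])
           # chain-align marker phases along the group so all codes
           # refer to one parental strand: flip a marker when its calls
           # anti-correlate with the previous aligned marker
           if (nrow(z) > 1) {
             for (i in 2:nrow(z)) {
               s <- mean(z[i, ] * z[i - 1, ], na.rm = TRUE)
               if (!is.na(s) && s < 0) z[i, ] <- -z[i, ]
             }
           }
           d <- .expectedCodeGrid(g$position, z, step)
           d$markers <- g$marker
           d
         })
}

#' Simple interval mapping (Haley-Knott regression)
#'
#' At each grid position (default 1 cM step, marker positions included),
#' the expected testcross-class code given the flanking markers is
#' computed from Haldane transition probabilities and the trait is
#' regressed on it: `lod = (n/2) log10(RSS0 / RSS1)`, `pv = 1 -
#' RSS1/RSS0`, and the additive effect is half the difference between the
#' two fitted class means. At fully informative marker positions this
#' reduces exactly to single-marker regression.
#'
#' @param map a [GeneticMap-class] of one parent.
#' @param x the matching [TestcrossGenotypes-class].
#' @param trait named numeric vector (names = individual ids).
#' @param step grid step in cM (default 1).
#' @return a LOD-profile data.frame: `group`, `position`, `lod`, `pv`,
#'   `additive`, `nearestMarker`.
#' @export
intervalMapping <- function(map, x, trait, step = 1) {
  trait <- trait[individuals(x)]
  ok <- !is.na(trait)
  design <- .scanDesign(map, x[, ok], step)
  y <- trait[ok]
  n <- length(y)
  yc <- y - mean(y)
  rss0 <- sum(yc^2)
  constTrait <- rss0 < 1e-12
  out <- lapply(names(design), function(gn) {
    d <- design[[gn]]
    if (constTrait)
      return(data.frame(group = gn, position = d$grid, lod = 0, pv = 0,
                        additive = 0,
                        nearestMarker = d$markers[d$nearest]))
    xc <- d$X - rowMeans(d$X)
    sxx <- rowSums(xc^2)
    sxy <- as.vector(xc %*% yc)
    usable <- sxx > 1e-12
    if (any(!usable))
      warning("skipping ", sum(!usable), " monomorphic position(s) in ",
              gn, call. = FALSE)
    beta <- ifelse(usable, sxy / sxx, NA_real_)
    rss1 <- ifelse(usable, rss0 - sxy^2 / sxx, NA_real_)
    data.frame(group = gn, position = d$grid,
               lod = ifelse(usable, (n / 2) * log10(rss0 / rss1), NA),
               pv = ifelse(usable, 1 - rss1 / rss0, NA),
               additive = beta,
               nearestMarker = d$markers[d$nearest])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select MQM cofactors by backward elimination
#'
#' Fits the trait on all candidate markers jointly (missing calls coded
#' to the class mean) and iteratively removes the least significant
#' candidate with `p >= pKeep` until every retained cofactor is
#' significant at `pKeep`; collinear candidates (aliased coefficients)
#' are removed first, later-entered first.
#'
#' @param x a [TestcrossGenotypes-class].
#' @param trait named numeric vector.
#' @param candidates candidate marker ids (typically one per putative
#'   QTL from the interval-mapping peaks).
#' @param pKeep retention threshold (default 0.02).
#' @return data.frame `marker`, `p` of the retained cofactors (possibly
#'   empty).
#' @export
selectCofactors <- function(x, trait, candidates, pKeep = 0.02) {
  trait <- trait[individuals(x)]
  ok <- !is.na(trait)
  z <- .zCode(calls(x)[candidates, ok, drop = FALSE])
  z[is.na(z)] <- 0
  y <- trait[ok]
  keep <- candidates
  repeat {
    if (!length(keep))
      return(data.frame(marker = character(), p = numeric()))
    X <- t(z[keep, , drop = FALSE])
    fit <- stats::lm(y ~ X)
    cf <- stats::coef(fit)[-1]
    if (anyNA(cf)) {                       # collinear: drop later-entered
      drop <- keep[max(which(is.na(cf)))]
      message("selectCofactors: dropping aliased cofactor ", drop)
      keep <- setdiff(keep, drop)
      next
    }
    pvals <- summary(fit)$coefficients[-1, 4]
    if (max(pvals) < pKeep)
      return(data.frame(marker = keep, p = unname(pvals)))
    keep <- keep[-which.max(pvals)]
  }
}

#' Multiple-QTL mapping scan with marker cofactors
#'
#' The interval-mapping regression augmented with cofactor genotypes as
#' covariates absorbing background genetic variance. Cofactors mapped on
#' the scanned group within `exclusionWindow` cM of the test position are
#' omitted from the covariate set (no self-fitting); with no cofactors
#' the scan equals [intervalMapping()]. `lod` and `pv` are computed
#' against the cofactor-reduced residual.
#'
#' @param map,x,trait,step as in [intervalMapping()].
#' @param cofactors data.frame from [selectCofactors()] (or a character
#'   vector of marker ids).
#' @param exclusionWindow cM window around the test position (default 20).
#' @return a LOD-profile data.frame as in [intervalMapping()].
#' @export
mqmScan <- function(map, x, trait, cofactors, exclusionWindow = 20,
                    step = 1) {
  cof <- if (is.data.frame(cofactors)) cofactors$marker else cofactors
  if (!length(cof)) return(intervalMapping(map, x, trait, step))
  trait <- trait[individuals(x)]
  ok <- !is.na(trait)
  xs <- x[, ok]
  y <- trait[ok]
  n <- length(y)
  design <- .scanDesign(map, xs, step)
  zCof <- .zCode(calls(xs)[cof, , drop = FALSE])
  zCof[is.na(zCof)] <- 0
  tb <- mapTable(map)
  cofGroup <- tb$group[match(cof, tb$marker)]
  cofPos <- tb$position[match(cof, tb$marker)]
  out <- lapply(names(design), function(gn) {
    d <- design[[gn]]
    res <- lapply(seq_along(d$grid), function(k) {
      p <- d$grid[k]
      use <- is.na(cofGroup) | cofGroup != gn |
        abs(cofPos - p) > exclusionWindow
      C <- if (any(use)) t(zCof[use, , drop = FALSE]) else NULL
      xq <- d$X[k, ]
      if (stats::var(xq) < 1e-12)
        return(c(NA, NA, NA))
      if (is.null(C)) {                     # all cofactors excluded: SIM
        rss0 <- sum((y - mean(y))^2)
        f1 <- stats::lm.fit(cbind(1, xq), y)
        rss1 <- sum(f1$residuals^2)
        return(c((n / 2) * log10(rss0 / rss1), 1 - rss1 / rss0,
                 f1$coefficients[2]))
      }
      fr <- stats::lm.fit(cbind(1, C), y)
      rss0 <- sum(fr$residuals^2)
      ff <- stats::lm.fit(cbind(1, C, xq), y)
      rss1 <- sum(ff$residuals^2)
      c((n / 2) * log10(rss0 / rss1), 1 - rss1 / rss0,
        ff$coefficients[length(ff$coefficients)])
    })
    res <- do.call(rbind, res)
    data.frame(group = gn, position = d$grid, lod = res[, 1],
               pv = res[, 2], additive = res[, 3],
               nearestMarker = d$markers[d$nearest])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the trait across individuals `nPerm` times, records the
#' genome-wide maximum interval-mapping LOD of each permutation, and
#' returns the empirical `1 - alpha` quantile.
#'
#' @param map,x,trait,step as in [intervalMapping()].
#' @param nPerm number of permutations (study-scale default 1000; at
#'   least 100).
#' @param alpha genome-wide error rate (default 0.05).
#' @param seed optional integer seed for the permutation stream.
#' @return list with `threshold` and `maxLods` (length `nPerm`).
#' @export
permutationThreshold <- function(map, x, trait, nPerm = 1000,
                                 alpha = 0.05, seed = NULL, step = 1) {
  if (nPerm < 100) stop("nPerm must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  trait <- trait[individuals(x)]
  ok <- !is.na(trait)
  design <- .scanDesign(map, x[, ok], step)
  y <- trait[ok]
  n <- length(y)
  X <- do.call(rbind, lapply(design, `[[`, "X"))
  xc <- X - rowMeans(X)
  sx <- sqrt(rowSums(xc^2))
  usable <- sx > 1e-8
  xs <- xc[usable, , drop = FALSE] / sx[usable]
  Y <- replicate(nPerm, sample(y))
  yc <- sweep(Y, 2, colMeans(Y))
  ys <- sweep(yc, 2, sqrt(colSums(yc^2)), "/")
  r2 <- (xs %*% ys)^2
  maxLods <- apply(-(n / 2) * log10(1 - r2), 2, max)
  list(threshold = unname(stats::quantile(maxLods, 1 - alpha)),
       maxLods = maxLods)
}

# 1-LOD support interval around a peak index within one group's profile
.supportInterval <- function(pos, lod, peakIx) {
  thr <- lod[peakIx] - 1
  lo <- peakIx
  while (lo > 1 && !is.na(lod[lo - 1]) && lod[lo - 1] >= thr) lo <- lo - 1
  hi <- peakIx
  while (hi < length(lod) && !is.na(lod[hi + 1]) && lod[hi + 1] >= thr)
    hi <- hi + 1
  c(pos[lo], pos[hi])
}

#' Call QTL from a LOD profile
#'
#' Reports local maxima with LOD at or above the genome-wide threshold;
#' two maxima on a group merge into a single call unless separated by a
#' dip of more than 1 LOD (measured from the lower peak). Each call
#' carries its 1-LOD support interval (the maximal contiguous region with
#' LOD within 1 of the peak), the nearest mapped locus, `pv` (as a
#' percentage) and additive effect at the peak, and a name following the
#' `lb_<map>_<LG>_<yy>` convention.
#'
#' @param profile a LOD-profile data.frame from [intervalMapping()] or
#'   [mqmScan()].
#' @param threshold genome-wide LOD threshold.
#' @param mapName map label used in QTL names (e.g. `"TGdL"`).
#' @param year optional year for the name suffix.
#' @param trait trait acronym for the name (default `"lb"`).
#' @return data.frame of calls: `name`, `group`, `peakCm`, `nearestLocus`,
#'   `lod`, `pvPercent`, `additive`, `intervalLo`, `intervalHi`,
#'   `threshold` (possibly 0 rows).
#' @export
callQtls <- function(profile, threshold, mapName = "map", year = NULL,
                     trait = "lb") {
  calls <- list()
  for (gn in unique(profile$group)) {
    pr <- profile[profile$group == gn, , drop = FALSE]
    lod <- pr$lod; pos <- pr$position
    ok <- !is.na(lod)
    if (!any(ok)) next
    npts <- length(lod)
    isPeak <- vapply(seq_len(npts), function(i) {
      if (is.na(lod[i]) || lod[i] < threshold) return(FALSE)
      l <- if (i > 1) lod[i - 1] else -Inf
      r <- if (i < npts) lod[i + 1] else -Inf
      lod[i] >= max(l, r, na.rm = TRUE)
    }, logical(1))
    peaks <- which(isPeak)
    if (!length(peaks)) next
    # merge peaks not separated by a dip > 1 LOD (from the lower peak)
    merged <- peaks[1]
    if (length(peaks) > 1) {
      for (pk in peaks[-1]) {
        prev <- merged[length(merged)]
        valley <- min(lod[prev:pk], na.rm = TRUE)
        if (min(lod[prev], lod[pk]) - valley > 1)
          merged <- c(merged, pk)
        else if (lod[pk] > lod[prev])
          merged[length(merged)] <- pk
      }
    }
    for (pk in merged) {
      ci <- .supportInterval(pos, lod, pk)
      calls[[length(calls) + 1]] <- data.frame(
        group = gn, peakCm = pos[pk],
        nearestLocus = pr$nearestMarker[pk], lod = lod[pk],
        pvPercent = 100 * pr$pv[pk], additive = pr$additive[pk],
        intervalLo = ci[1], intervalHi = ci[2], threshold = threshold)
    }
  }
  if (!length(calls))
    return(data.frame(name = character(), group = character(),
                      peakCm = numeric(), nearestLocus = character(),
                      lod = numeric(), pvPercent = numeric(),
                      additive = numeric(), intervalLo = numeric(),
                      intervalHi = numeric(), threshold = numeric()))
  out <- do.call(rbind, calls)
  suffix <- if (is.null(year)) "" else
    sprintf("_%02d", as.integer(year) %% 100)
  # group names that already carry the map prefix are not doubled
  lg <- ifelse(startsWith(out$group, paste0(mapName, "_")),
               sub(paste0("^", mapName, "_"), "", out$group), out$group)
  out <- cbind(name = sprintf("%s_%s_%s%s", trait, mapName, lg, suffix),
               out)
  rownames(out) <- NULL
  out
}
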