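#' Two-point recombination fraction and LOD for a testcross marker pair
#'
#' Over pairwise-complete individuals, counts mismatches `m` among `n`
#' comparisons; the phase-free recombinant count is `R = min(m, n - m)`,
#' the estimate is `R / n`, and the phase is coupling when `m <= n - m`,
#' repulsion otherwise. The two-point LOD against independence is
#' `(n - R) log10(2 (1 - r)) + R log10(2 r)`, equal to `n log10 2` when
#' no recombinants are observed.
#'
#' @param callsA,callsB character vectors of calls in \{"a","b",NA\} for
#'   two markers scored in the same parent.
#' @param lowInfoFloor flag the estimate low-confidence below this many
#'   informative individuals (default 20).
#' @return list with `rhat`, `phase`, `nInformative`, `lod`,
#'   `recombinants`, `lowConfidence`.
#' @examples
#' a <- rep(c("a", "b"), 50)
#' pairwiseRf(a, a)  # r = 0, coupling, lod = 100 * log10(2)
#' @export
pairwiseRf <- function(callsA, callsB, lowInfoFloor = 20) {
  stopifnot(length(callsA) == length(callsB))
  ok <- !is.na(callsA) & !is.na(callsB)
  n <- sum(ok)
  if (n == 0) stop("no pairwise-complete individuals: no information")
  m <- sum(callsA[ok] != callsB[ok])
  R <- min(m, n - m)
  r <- R / n
  lod <- if (R == 0) n * log10(2)
    else (n - R) * log10(2 * (1 - r)) + R * log10(2 * r)
  list(rhat = r, phase = if (m <= n - m) "coupling" else "repulsion",
       nInformative = n, lod = lod, recombinants = R,
       lowConfidence = n < lowInfoFloor)
}

#' All pairwise recombination fractions of a genotype set
#'
#' Matrix formulation of [pairwiseRf()] over every marker pair (equal
#' results, computed via cross-products of the 0/1-coded call and
#' missingness matrices).
#'
#' @param x a [TestcrossGenotypes-class] or a character call matrix
#'   (markers x individuals).
#' @return list of marker-by-marker matrices: `r`, `lod`, `n`
#'   (pairwise-complete counts), `coupling` (logical phase). Pairs with
#'   no shared information get an `NA` fraction and `lod = 0`.
#' @export
pairwiseRfMatrix <- function(x) {
  cl <- if (is(x, "TestcrossGenotypes")) calls(x) else x
  ids <- rownames(cl)
  X <- matrix(0, nrow(cl), ncol(cl)); X[cl == "b"] <- 1
  M <- (!is.na(cl)) * 1
  X[M == 0] <- 0
  nShared <- tcrossprod(M)
  half <- tcrossprod(X, M - X)
  mism <- half + t(half)
  R <- pmin(mism, nShared - mism)
  r <- R / nShared                     # NaN where nShared == 0
  r[nShared == 0] <- NA_real_
  t1 <- (nShared - R) * log10(2 * (1 - r))
  t2 <- R * log10(2 * r)
  t2[R == 0] <- 0                      # lim R->0 of R log(2r)
  lod <- t1 + t2
  lod[is.na(lod)] <- 0
  dimnames(r) <- dimnames(lod) <- dimnames(nShared) <- list(ids, ids)
  coupling <- mism <= nShared - mism
  dimnames(coupling) <- list(ids, ids)
  list(r = r, lod = lod, n = nShared, coupling = coupling)
}

#' Group markers into linkage groups by transitive LOD linkage
#'
#' Single-linkage (transitive closure) over edges with
#' `lod >= lodThreshold` and a recombination fraction at most `rmax`;
#' groups are returned in
#' decreasing size order.
#'
#' @param rf pairwise estimates from [pairwiseRfMatrix()].
#' @param lodThreshold grouping LOD threshold (the study-scale default
#'   for framework maps is 12).
#' @param rmax linkage cap on the recombination fraction (default 0.40).
#' @return list of marker-id vectors, largest group first.
#' @export
groupMarkers <- function(rf, lodThreshold = 12, rmax = 0.40) {
  p <- nrow(rf$r)
  ids <- rownames(rf$r)
  adj <- !is.na(rf$r) & rf$lod >= lodThreshold & rf$r <= rmax
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  edges <- which(adj, arr.ind = TRUE, useNames = FALSE)
  g <- igraph::make_empty_graph(n = p, directed = FALSE)
  if (nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  groups <- split(ids, comp)
  unname(groups[order(-lengths(groups))])
}

#' Kosambi map function
#'
#' Converts a recombination fraction to map distance,
#' `d = 25 ln((1 + 2r) / (1 - 2r))` cM, allowing for moderate crossover
#' interference. Strictly increasing on `[0, 0.5)`.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @return distance(s) in cM.
#' @examples
#' kosambiCm(0.1)   # 10.14 cM
#' kosambiCm(0.25)  # 27.47 cM
#' @export
kosambiCm <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("r must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Haldane map function and its inverse
#'
#' `haldaneCm(r) = -50 ln(1 - 2r)` cM assumes no interference;
#' `haldaneR(d) = (1 - exp(-2 d / 100)) / 2` inverts it. The simulator's
#' crossover process is Haldane, so these are the closed-form oracles for
#' simulated recombination fractions.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param d map distance(s) in cM.
#' @export
haldaneCm <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("r must lie in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' @rdname haldaneCm
#' @export
haldaneR <- function(d) {
  if (any(d < 0)) stop("distance must be nonnegative")
  (1 - exp(-2 * d / 100)) / 2
}

# vectorised best-improvement Or-opt: relocate one marker to its best
# insertion point (complements 2-opt, which cannot fix single-marker
# misplacements without reversing whole segments)
.orOptPass <- function(o, D) {
  n <- length(o)
  idx <- seq_len(n)
  prevO <- c(o[1], o[-n]); nextO <- c(o[-1], o[n])
  # gain of removing position i (boundary edges collapse)
  gain <- D[cbind(prevO, o)] + D[cbind(o, nextO)] -
    D[cbind(prevO, nextO)]
  gain[1] <- D[o[1], o[2]]
  gain[n] <- D[o[n - 1], o[n]]
  # cost of inserting marker i into gap j (between o[j] and o[j+1];
  # j = 0 prepends, j = n appends)
  edge <- c(0, D[cbind(o[-n], o[-1])], 0)         # gap costs, j = 0..n
  insA <- cbind(0, D[o, o, drop = FALSE])         # D[o[j], o[i]], j=0 pad
  insB <- cbind(D[o, o, drop = FALSE], 0)         # D[o[i], o[j+1]], j=n pad
  cost <- t(insA)[, idx, drop = FALSE] + t(insB)[, idx, drop = FALSE] -
    matrix(edge, n + 1, n)
  # row j+1 of cost = inserting each marker into gap j
  delta <- sweep(cost, 2, gain, "-")
  # forbid null moves (reinserting next to the original position)
  for (i in idx) delta[c(i, i + 1), i] <- Inf
  k <- arrayInd(which.min(delta), dim(delta))
  list(delta = delta[k], i = k[2], gap = k[1] - 1L)
}

.applyOrOpt <- function(o, i, gap) {
  x <- o[i]
  rest <- o[-i]
  if (gap > i - 1) gap <- gap - 1L      # gap index shifts after removal
  append(rest, x, after = gap)
}

# vectorised best-improvement 2-opt on a path with objective = sum of
# adjacent r; one pass evaluates every segment reversal via the two
# boundary edges it rewires
.twoOptPass <- function(o, D) {
  n <- length(o)
  prevEdge <- c(0, D[cbind(o[-n], o[-1])])          # C1[i] = D[o[i-1], o[i]]
  nextEdge <- c(D[cbind(o[-n], o[-1])], 0)          # C2[j] = D[o[j], o[j+1]]
  P <- c(o[1], o[-n])                               # o[i-1] (dummy at i=1)
  Nx <- c(o[-1], o[n])                              # o[j+1] (dummy at j=n)
  A <- D[P, o, drop = FALSE]; A[1, ] <- 0           # D[o[i-1], o[j]]
  B <- D[o, Nx, drop = FALSE]; B[, n] <- 0          # D[o[i], o[j+1]]
  delta <- A + B - outer(prevEdge, rep(1, n)) -
    outer(rep(1, n), nextEdge)
  delta[!upper.tri(delta)] <- Inf
  k <- arrayInd(which.min(delta), dim(delta))
  list(delta = delta[k], i = k[1], j = k[2])
}

#' Order the markers of a linkage group
#'
#' Seriates a group by minimising SARF (the sum of adjacent recombination
#' fractions): a greedy nearest-neighbour path is grown from the pair with
#' the smallest r by appending, at either end, the closest unplaced
#' marker, then refined by best-improvement 2-opt segment reversals to a
#' local optimum. The orientation is canonicalised so the lexicographically
#' smaller terminal marker id comes first. Missing pairwise estimates fall
#' back to `rmax` (logged).
#'
#' @param markers character vector of marker ids (>= 2).
#' @param rf pairwise estimates from [pairwiseRfMatrix()].
#' @param rmax fallback r for uninformative pairs (default 0.40).
#' @param randomStart start the 2-opt refinement from a random
#'   permutation (drawn from the current RNG stream) instead of the
#'   greedy nearest-neighbour path; useful for probing order stability.
#' @return list with `order` (marker ids) and `sarf`.
#' @export
orderGroup <- function(markers, rf, rmax = 0.40, randomStart = FALSE) {
  stopifnot(length(markers) >= 2)
  D <- rf$r[markers, markers, drop = FALSE]
  if (anyNA(D)) {
    message("orderGroup: ", sum(is.na(D[upper.tri(D)])),
            " uninformative pair(s) set to r = ", rmax)
    D[is.na(D)] <- rmax
  }
  n <- length(markers)
  if (n == 2)
    return(list(order = markers[order(markers)], sarf = D[1, 2]))
  if (randomStart) {
    path <- sample(n)
  } else {
    Dw <- D; diag(Dw) <- Inf
    seed <- arrayInd(which.min(Dw), dim(Dw))
    path <- as.integer(seed)
    free <- setdiff(seq_len(n), path)
    while (length(free)) {
      dHead <- Dw[path[1], free]
      dTail <- Dw[path[length(path)], free]
      if (min(dHead) <= min(dTail)) {
        path <- c(free[which.min(dHead)], path)
        free <- free[-which.min(dHead)]
      } else {
        path <- c(path, free[which.min(dTail)])
        free <- free[-which.min(dTail)]
      }
    }
  }
  repeat {
    improved <- FALSE
    repeat {
      mv <- .twoOptPass(path, D)
      if (!is.finite(mv$delta) || mv$delta > -1e-12) break
      path[mv$i:mv$j] <- rev(path[mv$i:mv$j])
      improved <- TRUE
    }
    repeat {
      mv <- .orOptPass(path, D)
      if (!is.finite(mv$delta) || mv$delta > -1e-12) break
      path <- .applyOrOpt(path, mv$i, mv$gap)
      improved <- TRUE
    }
    if (!improved) break
  }
  ord <- markers[path]
  if (ord[length(ord)] < ord[1]) ord <- rev(ord)
  sarf <- sum(D[cbind(path[-n], path[-1])])
  list(order = ord, sarf = sarf)
}

#' Build a genetic map from ordered linkage groups
#'
#' Positions are cumulative Kosambi distances over adjacent pairs from 0.
#' Per-marker distortion asterisks and a framework-order phase annotation
#' ("-r" for loci mapped in repulsion relative to the group's first
#' marker) are attached when available.
#'
#' @param orderedGroups named list of ordered marker-id vectors (names
#'   become linkage-group names; unnamed groups are numbered `LG_01`...).
#' @param rf pairwise estimates from [pairwiseRfMatrix()].
#' @param distortion optional [segregationClasses()]-style data.frame used
#'   to attach asterisks ("" for normal, "*" / "**" tiers).
#' @return a [GeneticMap-class].
#' @export
buildMap <- function(orderedGroups, rf, distortion = NULL) {
  if (is.null(names(orderedGroups)) || any(names(orderedGroups) == ""))
    names(orderedGroups) <- sprintf("LG_%02d", seq_along(orderedGroups))
  ast <- if (is.null(distortion)) NULL else
    stats::setNames(ifelse(distortion$class %in% c("*", "**"),
                           distortion$class, ""), distortion$marker)
  tabs <- lapply(names(orderedGroups), function(gn) {
    ids <- orderedGroups[[gn]]
    k <- length(ids)
    if (k == 1)
      return(data.frame(group = gn, marker = ids, position = 0,
                        asterisks = if (is.null(ast)) "" else
                          unname(ast[ids]),
                        phase = ""))
    adjR <- rf$r[cbind(ids[-k], ids[-1])]
    adjR[is.na(adjR)] <- 0.4
    pos <- cumsum(c(0, kosambiCm(pmin(adjR, 0.499))))
    coup <- rf$coupling[cbind(ids[-k], ids[-1])]
    relPhase <- cumprod(c(1, ifelse(coup, 1, -1)))
    data.frame(group = gn, marker = ids, position = pos,
               asterisks = if (is.null(ast)) "" else unname(ast[ids]),
               phase = ifelse(relPhase < 0, "-r", ""))
  })
  tb <- do.call(rbind, tabs)
  tb$asterisks[is.na(tb$asterisks)] <- ""
  GeneticMap(tb)
}

#' Distortion-robust pairwise association LOD
#'
#' Log10 likelihood-ratio (G-test) statistic of association in the 2x2
#' table of call classes, `G2 / (2 ln 10)`, computed for every marker
#' pair over pairwise-complete individuals. Unlike the testcross LOD of
#' [pairwiseRfMatrix()], which assumes 1:1 segregation, this statistic
#' conditions on the observed class margins, so markers with distorted
#' segregation (e.g. inside an arrangement-conditioned subpopulation of
#' a translocation cross) do not show spurious linkage.
#'
#' @param x a [TestcrossGenotypes-class] or character call matrix.
#' @return marker-by-marker matrix of association LODs (0 for pairs
#'   without information).
#' @export
pairwiseAssociationLod <- function(x) {
  cl <- if (is(x, "TestcrossGenotypes")) calls(x) else x
  A <- (cl == "a"); A[is.na(A)] <- FALSE; A <- A * 1
  B <- (cl == "b"); B[is.na(B)] <- FALSE; B <- B * 1
  n11 <- tcrossprod(A); n12 <- tcrossprod(A, B)
  n21 <- t(n12); n22 <- tcrossprod(B)
  n <- n11 + n12 + n21 + n22
  r1 <- n11 + n12; r2 <- n21 + n22
  c1 <- n11 + n21; c2 <- n12 + n22
  term <- function(o, e) ifelse(o > 0 & e > 0, o * log(o / e), 0)
  safe <- ifelse(n > 0, n, 1)
  g2 <- 2 * (term(n11, r1 * c1 / safe) + term(n12, r1 * c2 / safe) +
               term(n21, r2 * c1 / safe) + term(n22, r2 * c2 / safe))
  lod <- g2 / (2 * log(10))
  dimnames(lod) <- list(rownames(cl), rownames(cl))
  lod
}
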