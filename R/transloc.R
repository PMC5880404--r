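#' Scaffold bridges between two parental maps
#'
#' A scaffold bridges the maps when both place at least one marker from
#' it; bridges align linkage groups of the two single-parent maps of a
#' full-sib cross.
#'
#' @param mapA,mapB [GeneticMap-class] objects (e.g. female and male map).
#' @param scaffoldsA,scaffoldsB named character vectors, marker id ->
#'   scaffold, covering the markers of each map.
#' @return data.frame with columns `scaffold`, `groupA`, `groupB`.
#' @export
scaffoldBridges <- function(mapA, mapB, scaffoldsA, scaffoldsB) {
  ta <- mapTable(mapA); tb <- mapTable(mapB)
  a <- data.frame(scaffold = unname(scaffoldsA[ta$marker]),
                  groupA = ta$group)
  b <- data.frame(scaffold = unname(scaffoldsB[tb$marker]),
                  groupB = tb$group)
  out <- unique(merge(unique(a), unique(b), by = "scaffold"))
  out[order(out$scaffold), , drop = FALSE]
}

#' Detect pseudo-linkage between parental maps
#'
#' In a reciprocal-translocation heterozygote, markers of two
#' non-homologous chromosomes form a single spurious linkage group. A
#' group of map A is flagged as entangled when its scaffolds bridge to at
#' least two distinct groups of map B with at least `minBridges` bridges
#' each (the implicated pair being the two best-supported B groups).
#'
#' @param mapA,mapB [GeneticMap-class] objects; A is screened against the
#'   reference B.
#' @param bridges bridge table from [scaffoldBridges()].
#' @param minBridges minimum bridge support per implicated B group
#'   (default 5; single stray bridges from misassembled scaffolds must not
#'   trigger a flag).
#' @return list of flags, each `list(groupA, groupsB, bridgeCounts)`;
#'   empty when every A group corresponds to one B group.
#' @export
detectPseudoLinkage <- function(mapA, mapB, bridges, minBridges = 5) {
  if (nrow(bridges) == 0)
    stop("insufficient anchoring: no scaffold bridges between the maps")
  flags <- list()
  for (ga in unique(mapTable(mapA)$group)) {
    sub <- bridges[bridges$groupA == ga, , drop = FALSE]
    if (!nrow(sub)) next
    counts <- sort(table(sub$groupB), decreasing = TRUE)
    strong <- counts[counts >= minBridges]
    if (length(strong) >= 2)
      flags[[length(flags) + 1]] <- list(
        groupA = ga, groupsB = names(strong)[1:2],
        bridgeCounts = as.integer(strong)[1:2])
  }
  flags
}

#' Principal coordinate embedding of entangled markers
#'
#' Classical metric multidimensional scaling of the marker-by-marker
#' recombination-fraction matrix (the complement of the simple matching
#' similarity): squared distances are double-centred and
#' eigendecomposed; coordinates are eigenvectors scaled by the square
#' root of their eigenvalues. The share of variance per axis is reported
#' over the positive eigenvalues (summing to 100).
#'
#' @param markers character vector of marker ids (>= 3).
#' @param rf pairwise estimates from [pairwiseRfMatrix()].
#' @param k number of axes to keep (default 3).
#' @param rmaxImpute value for missing pairwise estimates (default 0.40).
#' @return list with `coordinates` (markers x axes), `eigenvalues`,
#'   `percentVariance`.
#' @export
pcoMarkers <- function(markers, rf, k = 3, rmaxImpute = 0.40) {
  if (length(markers) < 3)
    stop("degenerate embedding: need at least 3 markers")
  D <- rf$r[markers, markers, drop = FALSE]
  D[is.na(D)] <- rmaxImpute
  diag(D) <- 0
  k <- min(k, length(markers) - 1)
  mds <- suppressWarnings(stats::cmdscale(D, k = k, eig = TRUE))
  ev <- mds$eig
  pos <- ev[ev > 1e-12]
  pct <- if (length(pos)) 100 * ev[seq_len(k)] / sum(pos) else
    rep(0, k)
  pts <- mds$points
  if (is.null(dim(pts)) || ncol(pts) < k) {   # degenerate: pad with zeros
    pts <- cbind(pts, matrix(0, length(markers), k - ncol(pts)))
  }
  rownames(pts) <- markers
  list(coordinates = pts, eigenvalues = ev,
       percentVariance = pmax(pct, 0))
}

#' Map entangled markers onto the reference parent's map via scaffolds
#'
#' Each entangled marker of the carrier parent is assigned the linkage
#' group and cM position of the reference-map marker(s) sharing its
#' scaffold (mean position when several).
#'
#' @param markers entangled marker ids (carrier map).
#' @param scaffolds named vector marker id -> scaffold for those markers.
#' @param refMap the reference [GeneticMap-class].
#' @param refScaffolds named vector marker id -> scaffold for the
#'   reference map's markers.
#' @return data.frame `marker`, `refGroup`, `refPosition` (markers whose
#'   scaffold is absent from the reference map are omitted).
#' @export
referenceAssignments <- function(markers, scaffolds, refMap, refScaffolds) {
  tb <- mapTable(refMap)
  tb$scaffold <- unname(refScaffolds[tb$marker])
  agg <- stats::aggregate(position ~ scaffold + group, tb, mean)
  hit <- match(unname(scaffolds[markers]), agg$scaffold)
  ok <- !is.na(hit)
  data.frame(marker = markers[ok], refGroup = agg$group[hit[ok]],
             refPosition = agg$position[hit[ok]])
}

#' Locate the translocation breakpoints
#'
#' Among the entangled markers, finds the pair assigned to different
#' reference groups with the minimal recombination fraction; in a
#' translocation heterozygote the breakpoint-adjacent markers of the two
#' non-homologous chromosomes co-segregate, so the minimum-r cross-group
#' pair flanks the breakpoints. Ties are broken by larger informative
#' count, then lexicographic ids.
#'
#' @param refAssign assignments from [referenceAssignments()], covering
#'   two reference groups.
#' @param rf pairwise estimates from [pairwiseRfMatrix()].
#' @param rmaxDeclare declaration threshold: if the minimal cross-group r
#'   exceeds it, no translocation is declared and `NULL` is returned with
#'   a message (default 0.35).
#' @return a [BreakpointCall-class], or `NULL` (no-translocation finding).
#' @export
locateBreakpoint <- function(refAssign, rf, rmaxDeclare = 0.35) {
  grp <- unique(refAssign$refGroup)
  if (length(grp) < 2)
    stop("assignment error: entangled markers cover fewer than two ",
         "reference groups")
  mA <- refAssign$marker[refAssign$refGroup == grp[1]]
  mB <- refAssign$marker[refAssign$refGroup == grp[2]]
  R <- rf$r[mA, mB, drop = FALSE]
  N <- rf$n[mA, mB, drop = FALSE]
  cand <- which(!is.na(R), arr.ind = TRUE)
  if (!nrow(cand)) stop("assignment error: no informative cross-group pairs")
  o <- order(R[cand], -N[cand], mA[cand[, 1]], mB[cand[, 2]])
  best <- cand[o[1], , drop = FALSE]
  rmin <- R[best]
  if (rmin > rmaxDeclare) {
    message("minimum cross-group r = ", round(rmin, 3), " exceeds ",
            rmaxDeclare, ": no translocation declared")
    return(NULL)
  }
  a <- mA[best[1]]; b <- mB[best[2]]
  new("BreakpointCall",
      markerA = a, markerB = b,
      groupA = grp[1], groupB = grp[2],
      positionA = refAssign$refPosition[refAssign$marker == a][1],
      positionB = refAssign$refPosition[refAssign$marker == b][1],
      rhat = unname(rmin), nInformative = as.integer(N[best]))
}

# expected call under the translocated arrangement for marker w, given the
# anchor's translocated allele and the w-anchor phase
.expectedAllele <- function(anchorAllele, coupling) {
  ifelse(coupling, anchorAllele, ifelse(anchorAllele == "a", "b", "a"))
}

#' Split the F1 population by transmitted arrangement
#'
#' Labels each individual by the arrangement allele transmitted at the
#' two breakpoint-anchor markers: `"translocated"` (carrier-parent
#' arrangement, e.g. 9a-10b/10a-9b) or `"normal"`. All markers within
#' `windowCm` of either breakpoint on the reference map must support a
#' single arrangement; individuals with conflicting window evidence, or
#' missing calls at both anchors, are discarded with a reason.
#'
#' @param x the carrier-parent [TestcrossGenotypes-class].
#' @param bp a [BreakpointCall-class].
#' @param refAssign reference assignments of the entangled markers (used
#'   to find window markers).
#' @param rf pairwise estimates from [pairwiseRfMatrix()] (phases anchor
#'   the window markers to the breakpoint pair).
#' @param windowCm conflict-vetting window around each breakpoint
#'   (default 5 cM).
#' @param translocatedAllele the call at the first anchor marker that
#'   tags the translocated arrangement. The testcross coding of GBS calls
#'   is arbitrary, so this orientation cannot be inferred from progeny
#'   data alone; supply it from parent phase knowledge or simulation
#'   truth (default `"a"`).
#' @return a [SubpopAssignment-class].
#' @export
splitIndividuals <- function(x, bp, refAssign, rf, windowCm = 5,
                             translocatedAllele = "a") {
  cl <- calls(x)
  anchorA <- bp@markerA; anchorB <- bp@markerB
  tA <- translocatedAllele
  tB <- .expectedAllele(tA, rf$coupling[anchorA, anchorB])
  inWinA <- refAssign$refGroup == bp@groupA &
    abs(refAssign$refPosition - bp@positionA) <= windowCm
  inWinB <- refAssign$refGroup == bp@groupB &
    abs(refAssign$refPosition - bp@positionB) <= windowCm
  winA <- setdiff(refAssign$marker[inWinA], anchorA)
  winB <- setdiff(refAssign$marker[inWinB], anchorB)
  if (length(winA) + length(winB) + 2 == 0)
    stop("configuration error: empty breakpoint window")
  tWinA <- .expectedAllele(tA, rf$coupling[winA, anchorA])
  tWinB <- .expectedAllele(tB, rf$coupling[winB, anchorB])
  voters <- c(anchorA, anchorB, winA, winB)
  expected <- c(tA, tB, tWinA, tWinB)
  votes <- cl[voters, , drop = FALSE] ==
    matrix(expected, length(voters), ncol(cl))
  anchorVotes <- votes[1:2, , drop = FALSE]
  lab <- reason <- character(ncol(cl))
  for (i in seq_len(ncol(cl))) {
    av <- anchorVotes[, i]; v <- votes[, i]
    if (all(is.na(av))) {
      lab[i] <- "discarded"; reason[i] <- "missing calls at both anchors"
    } else if (length(unique(stats::na.omit(v))) > 1) {
      lab[i] <- "discarded"
      reason[i] <- "conflicting arrangement within breakpoint window"
    } else {
      lab[i] <- if (isTRUE(all(stats::na.omit(v)))) "translocated"
        else "normal"
      reason[i] <- ""
    }
  }
  new("SubpopAssignment", assignments = data.frame(
    individual = colnames(cl), label = lab, reason = reason))
}

# refine two partitions of the same marker set into their intersection
# cells. Markers grouped (size >= 2) in both partitions must agree in
# both — a spurious single-linkage merge in one subpopulation is undone
# by the other; markers grouped in only one subpopulation (the other
# being silent: near-monomorphic there, e.g. on a short arm with few
# observed crossovers) form wildcard cells carried by the informative
# subpopulation alone. Markers grouped in neither are leftovers.
.partitionCells <- function(p1, p2, ids) {
  keyOf <- function(p) {
    big <- p[lengths(p) >= 2]
    k <- rep("-", length(ids))
    names(k) <- ids
    for (i in seq_along(big)) {
      m <- intersect(big[[i]], ids)
      k[m] <- as.character(i)
    }
    k
  }
  k1 <- keyOf(p1); k2 <- keyOf(p2)
  key <- paste(k1, k2)
  cells <- split(ids, key)
  cells <- cells[names(cells) != "- -"]
  cells[order(-lengths(cells))]
}

# allocate the one missing arm from the reference map: identify which
# (reference group, breakpoint side) combination the three supported
# cores do not cover, and collect the unassigned entangled markers whose
# scaffold anchors fall there
.referenceFallbackArm <- function(cores, entangled, refAssign, bp) {
  rg <- stats::setNames(refAssign$refGroup, refAssign$marker)
  rp <- stats::setNames(refAssign$refPosition, refAssign$marker)
  bpPos <- stats::setNames(c(bp@positionA, bp@positionB),
                           c(bp@groupA, bp@groupB))
  comboOf <- function(m) {
    g <- rg[m]
    ifelse(is.na(g), NA_character_,
           paste(g, ifelse(rp[m] <= bpPos[g], "a", "b")))
  }
  coreCombo <- vapply(cores, function(core) {
    cc <- stats::na.omit(comboOf(core))
    if (!length(cc)) return(NA_character_)
    names(sort(table(cc), decreasing = TRUE))[1]
  }, character(1))
  all4 <- as.vector(outer(c(bp@groupA, bp@groupB), c("a", "b"), paste))
  missing <- setdiff(all4, coreCombo)
  if (length(missing) != 1 || anyNA(coreCombo)) return(NULL)
  free <- setdiff(entangled, unlist(cores))
  combo <- comboOf(free)
  cand <- free[!is.na(combo) & combo == missing]
  if (length(cand) >= 3) cand else NULL
}

# absorb one-sided (wildcard) cells into a two-sided cell from the same
# source group when full-population linkage supports it: such cells are
# usually breakpoint-proximal stragglers of an already-supported arm,
# but a short arm that one subpopulation cannot resolve (too few
# observed crossovers) stays standalone and can still become a core
.absorbStragglers <- function(cells, rGlobal, rCap = 0.25) {
  keys <- do.call(rbind, strsplit(names(cells), " "))
  twoSided <- keys[, 1] != "-" & keys[, 2] != "-"
  out <- as.list(cells)
  drop <- logical(length(cells))
  for (i in which(!twoSided)) {
    side <- if (keys[i, 1] != "-") 1 else 2
    mates <- which(twoSided & keys[, side] == keys[i, side])
    if (!length(mates)) next
    meanR <- vapply(mates, function(j)
      mean(rGlobal[cells[[i]], cells[[j]]], na.rm = TRUE), numeric(1))
    if (min(meanR, na.rm = TRUE) < rCap) {
      k <- mates[which.min(meanR)]
      out[[k]] <- c(out[[k]], cells[[i]])
      drop[i] <- TRUE
    }
  }
  cells <- out[!drop]
  cells[order(-lengths(cells))]
}

#' Rebuild the four chromosome arms of a translocation
#'
#' Runs linkage grouping independently within the translocated and normal
#' subpopulations (default LOD > 4): inside one subpopulation the
#' transmitted arrangement is fixed, so the entangled markers fall apart
#' into the four true arms. Markers severely distorted within a
#' subpopulation (chi-square beyond the alpha = 0.01 tier, the signature
#' of breakpoint proximity, where one arrangement's allele is nearly
#' fixed) and not consistently assignable across both subpopulations are
#' dropped; inconsistent but undistorted markers are rescued into the arm
#' whose members show the lower mean recombination fraction with them.
#'
#' @param x the carrier-parent [TestcrossGenotypes-class] (entangled
#'   markers only or a superset; only `entangled` rows are used).
#' @param entangled marker ids of the entangled group.
#' @param subpop a [SubpopAssignment-class].
#' @param refAssign reference assignments (used to name arms
#'   `<refGroup>a`/`<refGroup>b`; `a` is the arm at lower reference cM).
#' @param lodThreshold within-subpopulation grouping LOD (default 4).
#' @param rmax linkage cap (default 0.40).
#' @param bp optional [BreakpointCall-class]. When given and the
#'   subpopulations resolve only three arms (a short arm can be silent
#'   in both when few of its markers survive the distortion screen or
#'   few crossovers separate it from the breakpoint), the missing arm
#'   is allocated from the reference map: the markers whose scaffold
#'   anchors fall in the reference group and breakpoint side not
#'   covered by the three supported arms.
#' @return an [ArmSet-class]; reconstruction failure (other than 4 stable
#'   arms) raises an error carrying diagnostics.
#' @export
rebuildArms <- function(x, entangled, subpop, refAssign,
                        lodThreshold = 4, rmax = 0.40, bp = NULL) {
  asg <- assignments(subpop)
  subInds <- split(asg$individual, asg$label)
  if (is.null(subInds$translocated) || is.null(subInds$normal) ||
      !length(subInds$translocated) || !length(subInds$normal))
    stop("both subpopulations must be non-empty")
  cl <- calls(x)[entangled, , drop = FALSE]

  minMinor <- 5
  partOf <- function(inds) {
    sub <- cl[, inds, drop = FALSE]
    a <- rowSums(sub == "a", na.rm = TRUE)
    b <- rowSums(sub == "b", na.rm = TRUE)
    chi2 <- ifelse(a + b > 0, (a - b)^2 / (a + b), NA_real_)
    # near-fixed markers (breakpoint-proximal: one arrangement allele
    # almost monomorphic here) carry no grouping information and can
    # bridge arms through chance co-occurrence of their few minor calls
    usable <- pmin(a, b) >= minMinor
    sub <- sub[usable, , drop = FALSE]
    rfS <- pairwiseRfMatrix(sub)
    # inside a subpopulation the transmitted arrangement is fixed, so
    # segregation near the breakpoints is heavily distorted; grouping
    # uses the margin-conditioned association LOD, under which the four
    # arms are mutually independent while the testcross LOD would link
    # them spuriously through the skewed allele frequencies
    assoc <- list(r = rfS$r, lod = pairwiseAssociationLod(sub))
    groups <- groupMarkers(assoc, lodThreshold = lodThreshold,
                           rmax = rmax)
    groups <- c(groups, as.list(rownames(cl)[!usable]))
    list(groups = groups,
         distorted = rownames(cl)[!is.na(chi2) &
                                    chi2 > .CHI2_TIERS[["alpha01"]]])
  }
  p1 <- partOf(subInds$translocated)
  p2 <- partOf(subInds$normal)
  rfFull <- pairwiseRfMatrix(cl)
  cells <- .partitionCells(p1$groups, p2$groups, entangled)
  cells <- .absorbStragglers(cells, rfFull$r)
  cells <- cells[lengths(cells) >= 3]
  if (length(cells) == 3 && !is.null(bp)) {
    extra <- .referenceFallbackArm(cells, entangled, refAssign, bp)
    if (!is.null(extra)) cells <- c(cells, list(extra))
  }
  if (length(cells) < 4)
    stop("reconstruction failure: only ", length(cells),
         " stable marker cells across the two subpopulations")
  armCores <- unname(cells[1:4])

  consistent <- unlist(armCores)
  distortedAny <- union(p1$distorted, p2$distorted)
  leftovers <- setdiff(entangled, consistent)
  dropped <- intersect(leftovers, distortedAny)
  rescue <- setdiff(leftovers, dropped)
  if (length(rescue)) {
    for (m in rescue) {
      meanR <- vapply(armCores, function(core)
        mean(rfFull$r[m, core], na.rm = TRUE), numeric(1))
      k <- which.min(meanR)
      if (is.finite(meanR[k])) armCores[[k]] <- c(armCores[[k]], m)
      else dropped <- c(dropped, m)
    }
  }

  # arm names from the reference groups: two arms per reference group,
  # 'a' below the breakpoint (lower mean reference position)
  ra <- stats::setNames(refAssign$refGroup, refAssign$marker)
  rp <- stats::setNames(refAssign$refPosition, refAssign$marker)
  armGroup <- vapply(armCores, function(core) {
    g <- ra[intersect(core, names(ra))]
    names(sort(table(g), decreasing = TRUE))[1]
  }, character(1))
  armPos <- vapply(armCores, function(core)
    mean(rp[intersect(core, names(rp))], na.rm = TRUE), numeric(1))
  nm <- character(4)
  for (g in unique(armGroup)) {
    ix <- which(armGroup == g)
    ix <- ix[order(armPos[ix])]
    nm[ix] <- paste0(g, letters[seq_along(ix)])
  }
  if (anyDuplicated(nm) || length(unique(armGroup)) != 2)
    stop("reconstruction failure: arms do not map to two reference ",
         "groups (got ", paste(unique(armGroup), collapse = ", "), ")")
  names(armCores) <- nm
  new("ArmSet", arms = armCores[order(nm)], dropped = unique(dropped))
}
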