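#' Study-scale simulation configurations
#'
#' `translocationStudyConfig()` reproduces the mapping-population design
#' used throughout the validation studies: 11 chromosomes of 100 cM with
#' testcross markers every `spacing` cM in both parents, n individuals,
#' and the reciprocal translocation heterozygous in the female parent
#' between chromosomes 09 and 10 (breakpoints at 47 and 23 cM). Only
#' testcross SNP types are emitted (the non-segregating filler types play
#' no role in these studies).
#'
#' @param nIndividuals population size (default 213).
#' @param spacing marker spacing in cM (default 1).
#' @param translocation simulate the translocation (default TRUE).
#' @param qtls planted QTL data.frame or `NULL`.
#' @param seed integer seed.
#' @param ... passed to [simConfig()].
#' @return a `SimConfig`.
#' @export
translocationStudyConfig <- function(nIndividuals = 213, spacing = 1,
                                     translocation = TRUE, qtls = NULL,
                                     seed = 1L, ...) {
  armL <- c(rep(50, 8), 47, 23, 50)
  chroms <- lapply(1:11, function(i)
    list(name = sprintf("chr%02d", i), armLeft = armL[i],
         armRight = 100 - armL[i],
         markerPositions = seq(0, 100, by = spacing)))
  simConfig(nIndividuals, chroms,
            snpTypeMix = c(I = 0, II = 0, III = 0, IV = 0.5, V = 0.5),
            translocation = if (translocation) c("chr09", "chr10"),
            qtls = qtls, seed = seed, ...)
}

# true arm of a female marker, from the truth record
.trueArm <- function(ids, truth) {
  tm <- truth$femaleMap
  chr <- tm$chromosome[match(ids, tm$marker)]
  pos <- tm$cm[match(ids, tm$marker)]
  jn <- stats::setNames(truth$breakpoints$junction,
                        truth$breakpoints$chromosome)
  ifelse(chr == truth$breakpoints$chromosome[1],
         ifelse(pos <= jn[1], "A1", "A2"),
         ifelse(pos <= jn[2], "B1", "B2"))
}

#' Translocation-recovery simulation study
#'
#' For each seed: simulates the translocation cross
#' ([translocationStudyConfig()]), runs marker QC, grouping of the female
#' markers and reference (male) map construction, pseudo-linkage
#' detection, breakpoint localisation, subpopulation splitting and
#' four-arm reconstruction, and scores the outcome against the
#' simulation truth.
#'
#' @param seeds integer vector of seeds.
#' @param nIndividuals,spacing passed to [translocationStudyConfig()].
#' @param bpToleranceCm tolerance on breakpoint localisation, measured
#'   as the true-map distance between each called anchor marker and the
#'   true breakpoint of its chromosome (default 5 cM).
#' @return data.frame with one row per seed: `flaggedOne` (exactly one
#'   entangled female group flagged), `bpErrA`, `bpErrB` (cM), `bpOk`,
#'   `splitAccuracy` (non-discarded individuals matching the true
#'   arrangement), `nDiscarded`, `armsOk` (four arms rebuilt),
#'   `armPurity` (retained markers on their true arm), `success` (all
#'   of: one flag, both breakpoints within tolerance, split accuracy and
#'   arm purity at least 0.95).
#' @export
translocationRecoveryStudy <- function(seeds, nIndividuals = 213,
                                       spacing = 1, bpToleranceCm = 5) {
  out <- lapply(seeds, function(sd) {
    pop <- simulatePopulation(
      translocationStudyConfig(nIndividuals, spacing, seed = sd))
    row <- data.frame(seed = sd, flaggedOne = FALSE, bpErrA = NA_real_,
                      bpErrB = NA_real_, bpOk = FALSE,
                      splitAccuracy = NA_real_, nDiscarded = NA_integer_,
                      armsOk = FALSE, armPurity = NA_real_,
                      success = FALSE)
    qcF <- markerQc(pop$genotypes, "female")
    qcM <- markerQc(pop$genotypes, "male")
    rfF <- pairwiseRfMatrix(qcF$genotypes)
    gF <- groupMarkers(rfF, 12, 0.40)
    gF <- gF[lengths(gF) >= 2]
    names(gF) <- sprintf("F_%02d", seq_along(gF))
    fMap <- GeneticMap(data.frame(
      group = rep(names(gF), lengths(gF)),
      marker = unlist(gF, use.names = FALSE),
      position = unlist(lapply(lengths(gF), seq_len)) - 1,
      asterisks = ""))
    pmM <- buildParentMap(qcM$genotypes, 12, 0.40, "M")
    scafF <- stats::setNames(markerInfo(qcF$genotypes)$scaffold,
                             rownames(qcF$genotypes))
    scafM <- stats::setNames(markerInfo(qcM$genotypes)$scaffold,
                             rownames(qcM$genotypes))
    bridges <- scaffoldBridges(fMap, pmM$map, scafF, scafM)
    flags <- detectPseudoLinkage(fMap, pmM$map, bridges)
    row$flaggedOne <- length(flags) == 1
    if (!row$flaggedOne) return(row)
    flag <- flags[[1]]
    entangled <- gF[[flag$groupA]]
    refAssign <- referenceAssignments(entangled, scafF, pmM$map, scafM)
    refAssign <- refAssign[refAssign$refGroup %in% flag$groupsB, ,
                           drop = FALSE]
    bp <- locateBreakpoint(refAssign, rfF)
    if (is.null(bp)) return(row)
    tm <- pop$truth$femaleMap
    jn <- stats::setNames(pop$truth$breakpoints$junction,
                          pop$truth$breakpoints$chromosome)
    errOf <- function(mk) {
      chr <- tm$chromosome[tm$marker == mk]
      abs(tm$cm[tm$marker == mk] - jn[chr])
    }
    row$bpErrA <- errOf(bp@markerA); row$bpErrB <- errOf(bp@markerB)
    row$bpOk <- row$bpErrA <= bpToleranceCm && row$bpErrB <= bpToleranceCm
    phA <- pop$truth$phases$female[bp@markerA]
    sp <- splitIndividuals(qcF$genotypes, bp, refAssign, rfF,
                           translocatedAllele = if (phA == 2) "a" else "b")
    asg <- assignments(sp)
    ok <- asg$label != "discarded"
    row$splitAccuracy <-
      mean(asg$label[ok] == pop$truth$arrangement[asg$individual][ok])
    row$nDiscarded <- sum(!ok)
    armSet <- tryCatch(
      rebuildArms(qcF$genotypes, entangled, sp, refAssign,
                  lodThreshold = 4, rmax = 0.40, bp = bp),
      error = function(e) NULL)
    row$armsOk <- !is.null(armSet)
    if (row$armsOk) {
      a <- arms(armSet)
      correct <- vapply(a, function(ids) {
        ta <- .trueArm(ids, pop$truth)
        max(table(ta))
      }, numeric(1))
      row$armPurity <- sum(correct) / sum(lengths(a))
    }
    row$success <- row$flaggedOne && row$bpOk &&
      !is.na(row$splitAccuracy) && row$splitAccuracy >= 0.95 &&
      row$armsOk && !is.na(row$armPurity) && row$armPurity >= 0.95
    row
  })
  do.call(rbind, out)
}

# genetic map straight from the simulation truth (female markers)
.truthFemaleMap <- function(pop) {
  tm <- pop$truth$femaleMap
  tm <- tm[order(tm$chromosome, tm$cm), ]
  GeneticMap(data.frame(group = tm$chromosome, marker = tm$marker,
                        position = tm$cm, asterisks = ""))
}

#' QTL-recovery simulation study
#'
#' For each seed: simulates the mapping population with one planted
#' female-parent QTL of phenotypic-variance fraction `pv` (no
#' translocation), scans the true-map female markers by simple interval
#' mapping, computes the genome-wide permutation threshold, and scores
#' detection, 1-LOD-interval coverage of the true position and the
#' estimated variance fraction at the true position.
#'
#' @param seeds integer vector of seeds.
#' @param pv planted phenotypic-variance fraction (default 0.45).
#' @param nIndividuals population size (default 213).
#' @param spacing marker spacing in cM (default 1, the study design).
#' @param nPerm permutations per seed (default 200).
#' @param alpha genome-wide error rate (default 0.05).
#' @return data.frame per seed: `threshold`, `peakLod`, `detected`,
#'   `inInterval`, `pvHat` (at the true position), `pvErr`.
#' @export
qtlRecoveryStudy <- function(seeds, pv = 0.45, nIndividuals = 213,
                             spacing = 1, nPerm = 200, alpha = 0.05) {
  qtlPos <- 19
  a <- sqrt(pv / (1 - pv))              # residualSd = 1
  qtls <- data.frame(parent = "female", chromosome = "chr02",
                     position = qtlPos, additive = a)
  out <- lapply(seeds, function(sd) {
    pop <- simulatePopulation(
      translocationStudyConfig(nIndividuals, spacing,
                               translocation = FALSE, qtls = qtls,
                               seed = sd, residualSd = 1))
    mp <- .truthFemaleMap(pop)
    xg <- pop$genotypes[mapTable(mp)$marker, ]
    tv <- stats::setNames(pop$traits$trait, pop$traits$individual)
    perm <- permutationThreshold(mp, xg, tv, nPerm = nPerm,
                                 alpha = alpha, seed = sd)
    prof <- intervalMapping(mp, xg, tv, step = 1)
    calls <- callQtls(prof, perm$threshold, mapName = "F")
    onTrue <- calls[calls$group == "chr02", , drop = FALSE]
    best <- if (nrow(onTrue)) onTrue[which.max(onTrue$lod), ] else NULL
    atTrue <- prof[prof$group == "chr02", ]
    pvHat <- atTrue$pv[which.min(abs(atTrue$position - qtlPos))]
    data.frame(
      seed = sd, threshold = perm$threshold,
      peakLod = if (is.null(best)) max(prof$lod, na.rm = TRUE) else
        best$lod,
      detected = !is.null(best),
      inInterval = !is.null(best) && best$intervalLo <= qtlPos &&
        best$intervalHi >= qtlPos,
      pvHat = pvHat, pvErr = pvHat - pv)
  })
  do.call(rbind, out)
}

#' Null-genome QTL-scan calibration
#'
#' Simulates trait-free (pure-noise) populations and checks how often
#' the genome-wide maximum interval-mapping LOD exceeds the population's
#' own permutation threshold; calibration requires this to match `alpha`.
#'
#' @inheritParams qtlRecoveryStudy
#' @return data.frame per seed: `threshold`, `maxLod`, `exceeds`.
#' @export
nullQtlCalibration <- function(seeds, nIndividuals = 213, spacing = 1,
                               nPerm = 200, alpha = 0.05) {
  out <- lapply(seeds, function(sd) {
    pop <- simulatePopulation(
      translocationStudyConfig(nIndividuals, spacing,
                               translocation = FALSE, qtls = NULL,
                               seed = sd, residualSd = 1))
    mp <- .truthFemaleMap(pop)
    xg <- pop$genotypes[mapTable(mp)$marker, ]
    tv <- stats::setNames(pop$traits$trait, pop$traits$individual)
    perm <- permutationThreshold(mp, xg, tv, nPerm = nPerm,
                                 alpha = alpha, seed = sd)
    prof <- intervalMapping(mp, xg, tv, step = 1)
    mx <- max(prof$lod, na.rm = TRUE)
    data.frame(seed = sd, threshold = perm$threshold, maxLod = mx,
               exceeds = mx >= perm$threshold)
  })
  do.call(rbind, out)
}
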