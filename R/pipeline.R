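#' Build one parent's framework map
#'
#' Two-point estimation, LOD grouping, SARF ordering and Kosambi
#' positioning for the testcross markers of one parent. Groups are named
#' `<prefix>_01`... in decreasing size order; markers that join no group
#' (singletons at the grouping threshold) are reported separately.
#'
#' @param x a [TestcrossGenotypes-class] (one parent's framework
#'   markers, e.g. from [markerQc()]).
#' @param lodThreshold grouping LOD (default 12).
#' @param rmax linkage cap (default 0.40).
#' @param prefix linkage-group name prefix.
#' @return list with `map` ([GeneticMap-class]), `rf` (pairwise
#'   estimates), `groups` (marker-id lists), `ungrouped`.
#' @export
buildParentMap <- function(x, lodThreshold = 12, rmax = 0.40,
                           prefix = "LG") {
  rf <- pairwiseRfMatrix(x)
  groups <- groupMarkers(rf, lodThreshold = lodThreshold, rmax = rmax)
  ungrouped <- unlist(groups[lengths(groups) < 2])
  groups <- groups[lengths(groups) >= 2]
  names(groups) <- sprintf("%s_%02d", prefix, seq_along(groups))
  ordered <- lapply(groups, function(g) orderGroup(g, rf, rmax)$order)
  seg <- segregationClasses(x)
  map <- buildMap(ordered, rf, distortion = seg)
  list(map = map, rf = rf, groups = groups,
       ungrouped = as.character(ungrouped))
}

# orient an ordered arm (or group) so it runs in increasing reference
# position where reference anchors exist
.orientByReference <- function(ord, refAssign) {
  rp <- stats::setNames(refAssign$refPosition, refAssign$marker)
  anchored <- ord[ord %in% names(rp)]
  if (length(anchored) >= 2 &&
      stats::cor(seq_along(anchored), rp[anchored]) < 0)
    rev(ord) else ord
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages in order: simulate (or ingest) -> marker QC
#' per parent -> framework mapping per parent -> pseudo-linkage
#' detection against the male (reference) map, with breakpoint
#' localisation, subpopulation split and four-arm reconstruction when a
#' translocation is flagged -> QTL scan per trait year (interval
#' mapping, permutation threshold, cofactor selection, MQM, QTL calls).
#' Identical configuration and seed give identical results.
#'
#' @param config a `PipelineConfig` from [pipelineConfig()] (or a path
#'   to its JSON serialisation).
#' @param outDir optional directory; when given, all artifact tables are
#'   written there as tab-delimited files with the seed in their header.
#' @param translocatedAllele passed to [splitIndividuals()].
#' @return list of artifacts: `funnel`, `femaleMap`, `maleMap`,
#'   `summaries`, `pseudoLinkage`, `pco`, `breakpoint`, `subpops`,
#'   `arms`, `qtl` (per-year calls), `profiles`, `thresholds`, `truth`
#'   (simulation only).
#' @export
runPipeline <- function(config, outDir = NULL, translocatedAllele = "a") {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  res <- list(seed = config$seed)

  ## ingest / simulate
  if (length(config$simulate) || is.null(config$genotypes)) {
    simArgs <- config$simulate
    simArgs$seed <- config$seed
    simCfg <- do.call(defaultSimConfig, simArgs)
    pop <- simulatePopulation(simCfg)
    geno <- pop$genotypes
    traits <- pop$traits
    res$truth <- pop$truth
  } else {
    geno <- readGenotypes(config$genotypes)
    traits <- if (!is.null(config$traits)) readTraits(config$traits)
  }

  ## marker QC
  qcF <- markerQc(geno, "female", minOverlap = config$minOverlap)
  qcM <- markerQc(geno, "male", minOverlap = config$minOverlap)
  res$funnel <- rbind(
    data.frame(parent = "female", t(markerFunnel(qcF$genotypes))),
    data.frame(parent = "male", t(markerFunnel(qcM$genotypes))))
  if (!"qc" %in% config$stages || !"map" %in% config$stages)
    return(res)

  ## framework maps
  pmF <- buildParentMap(qcF$genotypes, config$lodGroup, config$rmax, "F")
  pmM <- buildParentMap(qcM$genotypes, config$lodGroup, config$rmax, "M")
  res$maleMap <- pmM$map
  res$femaleMap <- pmF$map

  ## pseudo-linkage detection and disentanglement
  if ("disentangle" %in% config$stages) {
    scafF <- stats::setNames(markerInfo(qcF$genotypes)$scaffold,
                             rownames(qcF$genotypes))
    scafM <- stats::setNames(markerInfo(qcM$genotypes)$scaffold,
                             rownames(qcM$genotypes))
    bridges <- scaffoldBridges(pmF$map, pmM$map, scafF, scafM)
    flags <- detectPseudoLinkage(pmF$map, pmM$map, bridges,
                                 minBridges = config$minBridges)
    res$pseudoLinkage <- flags
    if (length(flags) == 1) {
      flag <- flags[[1]]
      tbF <- mapTable(pmF$map)
      entangled <- tbF$marker[tbF$group == flag$groupA]
      refAssign <- referenceAssignments(entangled, scafF, pmM$map, scafM)
      refAssign <- refAssign[refAssign$refGroup %in% flag$groupsB, ,
                             drop = FALSE]
      res$pco <- pcoMarkers(refAssign$marker, pmF$rf)
      bp <- locateBreakpoint(refAssign, pmF$rf,
                             rmaxDeclare = config$rmaxDeclare)
      res$breakpoint <- bp
      if (!is.null(bp)) {
        sp <- splitIndividuals(qcF$genotypes, bp, refAssign, pmF$rf,
                               windowCm = config$windowCm,
                               translocatedAllele = translocatedAllele)
        res$subpops <- sp
        armSet <- tryCatch(
          rebuildArms(qcF$genotypes, entangled, sp, refAssign,
                      lodThreshold = config$lodArms, rmax = config$rmax,
                      bp = bp),
          error = function(e) e)
        if (inherits(armSet, "error")) {
          # reconstruction failure: keep the entangled group, report
          res$reconstructionFailure <- conditionMessage(armSet)
        } else {
          res$arms <- armSet
          ## final female map: intact groups + the four arms ordered on
          ## the full population
          intact <- split(tbF$marker, tbF$group)
          intact <- intact[names(intact) != flag$groupA]
          armOrders <- lapply(arms(armSet), function(ids) {
            if (length(ids) < 2) return(ids)
            ord <- orderGroup(ids, pmF$rf, config$rmax)$order
            .orientByReference(ord, refAssign)
          })
          allGroups <- c(intact, armOrders)
          seg <- segregationClasses(qcF$genotypes)
          res$femaleMap <- buildMap(allGroups, pmF$rf, distortion = seg)
        }
      }
    }
  }
  res$summaries <- list(female = mapSummary(res$femaleMap),
                        male = mapSummary(res$maleMap))

  ## QTL scan per trait year, on both parental maps
  if ("scan" %in% config$stages && !is.null(traits)) {
    res$qtl <- list(); res$profiles <- list(); res$thresholds <- list()
    res$phenotypes <- list()
    years <- sort(unique(traits$year))
    for (yi in seq_along(years)) {
      yr <- years[yi]
      tv <- traits$trait[traits$year == yr]
      names(tv) <- traits$individual[traits$year == yr]
      res$phenotypes[[as.character(yr)]] <- summarizePhenotype(tv)
      for (side in c("female", "male")) {
        mp <- if (side == "female") res$femaleMap else res$maleMap
        xg <- if (side == "female") qcF$genotypes else qcM$genotypes
        permSeed <- config$seed + 7919L * yi +
          1000003L * (side == "male")
        perm <- permutationThreshold(mp, xg, tv, nPerm = config$nPerm,
                                     alpha = config$alpha,
                                     seed = permSeed,
                                     step = config$step)
        sim <- intervalMapping(mp, xg, tv, step = config$step)
        mapName <- if (side == "female") "F" else "M"
        simCalls <- callQtls(sim, perm$threshold, mapName = mapName,
                             year = yr)
        cof <- if (nrow(simCalls))
          selectCofactors(xg, tv, unique(simCalls$nearestLocus),
                          pKeep = config$pKeep)
        else data.frame(marker = character(), p = numeric())
        mqm <- mqmScan(mp, xg, tv, cof,
                       exclusionWindow = config$exclusionWindow,
                       step = config$step)
        finalCalls <- callQtls(mqm, perm$threshold, mapName = mapName,
                               year = yr)
        key <- paste(side, yr, sep = "_")
        res$thresholds[[key]] <- perm$threshold
        res$profiles[[key]] <- mqm
        res$qtl[[key]] <- finalCalls
        res$cofactors[[key]] <- cof
      }
    }
  }

  if (!is.null(outDir)) writePipelineOutputs(res, outDir)
  res
}

#' Write pipeline artifacts to a directory
#'
#' Emits the tab-delimited artifact tables (QC funnel, maps and their
#' summaries, subpopulation assignments, arm memberships, PCO
#' coordinates, LOD profiles and the QTL report), each with the seed
#' recorded in a `#` header line.
#'
#' @param res result list from [runPipeline()].
#' @param outDir output directory (created if absent).
#' @return `outDir`, invisibly.
#' @export
writePipelineOutputs <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hdr <- paste("seed:", res$seed)
  wt <- function(df, name) {
    p <- file.path(outDir, name)
    con <- file(p, "w"); on.exit(close(con), add = TRUE)
    writeLines(paste("#", hdr), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(res$funnel)) wt(res$funnel, "qc_funnel.tsv")
  if (!is.null(res$femaleMap))
    writeMap(res$femaleMap, file.path(outDir, "map_female.tsv"), hdr)
  if (!is.null(res$maleMap))
    writeMap(res$maleMap, file.path(outDir, "map_male.tsv"), hdr)
  if (!is.null(res$summaries)) {
    s <- rbind(cbind(parent = "female", res$summaries$female),
               cbind(parent = "male", res$summaries$male))
    wt(s, "map_summary.tsv")
  }
  if (!is.null(res$subpops)) wt(assignments(res$subpops),
                                "subpopulations.tsv")
  if (!is.null(res$arms)) {
    a <- arms(res$arms)
    wt(data.frame(arm = rep(names(a), lengths(a)),
                  marker = unlist(a, use.names = FALSE)), "arms.tsv")
  }
  if (!is.null(res$pco))
    wt(data.frame(marker = rownames(res$pco$coordinates),
                  res$pco$coordinates), "pco.tsv")
  if (!is.null(res$qtl) && length(res$qtl)) {
    allCalls <- do.call(rbind, Map(function(k, v)
      if (nrow(v)) cbind(scan = k, v), names(res$qtl), res$qtl))
    if (!is.null(allCalls) && nrow(allCalls))
      wt(allCalls, "qtl_report.tsv")
    profs <- do.call(rbind, Map(function(k, v) cbind(scan = k, v),
                                names(res$profiles), res$profiles))
    wt(profs, "lod_profiles.tsv")
  }
  invisible(outDir)
}
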