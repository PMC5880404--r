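#' Simulation configuration for an F1 pseudo-testcross population
#'
#' Describes the cross to simulate: population size, chromosome/arm
#' geometry with marker positions, the SNP-type composition, an optional
#' reciprocal translocation heterozygous in the female parent (breakpoints
#' at the arm junctions), planted QTL, and the trait model.
#'
#' Each marker position hosts one genome scaffold carrying a
#' female-testcross (type IV) and a male-testcross (type V) SNP, so both
#' parental maps have the same nominal density and the two maps can be
#' aligned through shared scaffolds. Non-testcross SNP types (I, II, III)
#' are added as filler loci on their own scaffolds so the overall type
#' composition approximates `snpTypeMix`; they carry no mappable testcross
#' calls (types I/II are monomorphic in coded calls, type III intercross
#' calls are not representable in the two-symbol testcross coding and are
#' emitted as missing).
#'
#' @param nIndividuals number of F1 individuals (>= 2).
#' @param chromosomes list of chromosome descriptions; each element a list
#'   with `name`, `armLeft` and `armRight` (arm lengths in cM; the arm
#'   junction sits at `armLeft`), and `markerPositions` (cM from the left
#'   end, within `[0, armLeft + armRight]`).
#' @param snpTypeMix named proportions over SNP types I-V, summing to 1.
#' @param translocation `NULL`, or a length-2 character vector naming the
#'   chromosome pair that is reciprocally translocated (heterozygous) in
#'   the female parent, with breakpoints at the two arm junctions.
#' @param qtls data.frame with columns `parent` ("female"/"male"),
#'   `chromosome`, `position` (cM) and `additive` (trait units); the
#'   transmitted allele contributes +/- `additive` to the genetic value.
#' @param traitMean,residualSd trait model intercept and residual SD
#'   (trait units).
#' @param ratingScale if `TRUE`, traits are binned to the ordinal 1-9
#'   phenology scale by equal-width bins over the population range.
#' @param years number of phenotyping years; years share genetic values
#'   and differ by independent residual draws.
#' @param missingRate,errorRate genotyping-noise rates in `[0, 1)`.
#' @param seed integer seed; all stochastic draws flow from one generator
#'   stream seeded once with it.
#' @return a validated `SimConfig` list.
#' @seealso [defaultSimConfig()], [simulatePopulation()]
#' @export
simConfig <- function(nIndividuals, chromosomes,
                      snpTypeMix = c(I = 0, II = 0, III = 0,
                                     IV = 0.5, V = 0.5),
                      translocation = NULL, qtls = NULL,
                      traitMean = 4.5, residualSd = 1, ratingScale = FALSE,
                      years = 1L, missingRate = 0, errorRate = 0,
                      seed = 1L) {
  stopifnot(nIndividuals >= 2, length(chromosomes) >= 1)
  if (abs(sum(snpTypeMix) - 1) > 1e-8)
    stop("snpTypeMix must sum to 1")
  if (missingRate < 0 || missingRate >= 1 || errorRate < 0 || errorRate >= 1)
    stop("missingRate and errorRate must lie in [0, 1)")
  chrNames <- vapply(chromosomes, `[[`, character(1), "name")
  if (anyDuplicated(chrNames)) stop("duplicate chromosome names")
  for (ch in chromosomes) {
    len <- ch$armLeft + ch$armRight
    if (any(ch$markerPositions < 0 | ch$markerPositions > len))
      stop("marker positions outside chromosome '", ch$name, "'")
  }
  if (!is.null(translocation)) {
    if (length(translocation) != 2 || !all(translocation %in% chrNames))
      stop("translocation must name two simulated chromosomes")
  }
  if (!is.null(qtls)) {
    stopifnot(all(c("parent", "chromosome", "position", "additive") %in%
                    colnames(qtls)))
    for (i in seq_len(nrow(qtls))) {
      ch <- chromosomes[[match(qtls$chromosome[i], chrNames)]]
      if (is.na(ch$name[1]) || qtls$position[i] < 0 ||
          qtls$position[i] > ch$armLeft + ch$armRight)
        stop("QTL position outside its chromosome")
    }
    pv <- qtls$additive^2 /
      (sum(qtls$additive^2) + residualSd^2)
    if (any(pv <= 0 | pv >= 1))
      stop("QTL phenotypic variance fraction outside (0, 1)")
  }
  structure(list(
    nIndividuals = as.integer(nIndividuals), chromosomes = chromosomes,
    snpTypeMix = snpTypeMix, translocation = translocation,
    qtls = qtls, traitMean = traitMean, residualSd = residualSd,
    ratingScale = ratingScale, years = as.integer(years),
    missingRate = missingRate, errorRate = errorRate,
    seed = as.integer(seed)
  ), class = "SimConfig")
}

#' Study-scale default simulation configuration
#'
#' Emulates the hazelnut TGdL x MB mapping design: 213 genotyped F1
#' individuals; 11 chromosomes of 100 cM with testcross markers every
#' `spacing` cM; a reciprocal translocation heterozygous in the female
#' parent between chromosomes 09 and 10 with breakpoints at 47 and 23 cM;
#' one major female QTL on chromosome 02 at 19 cM plus two minor QTL; a
#' 1-9 phenology-style trait with mean 4.5 and total SD about 1.5, of
#' which the major QTL explains about 45%.
#'
#' @param nIndividuals population size (default 213).
#' @param spacing marker spacing in cM (default 1).
#' @param translocation simulate the translocation (default TRUE).
#' @param qtls override the default planted QTL (`NULL` keeps defaults;
#'   `NA` removes all QTL).
#' @param seed integer seed.
#' @param ... further arguments passed to [simConfig()].
#' @return a `SimConfig`.
#' @export
defaultSimConfig <- function(nIndividuals = 213, spacing = 1,
                             translocation = TRUE, qtls = NULL,
                             seed = 1L, ...) {
  armL <- c(50, 50, 50, 50, 50, 50, 50, 50, 47, 23, 50)
  armR <- c(50, 50, 50, 50, 50, 50, 50, 50, 53, 77, 50)
  chroms <- lapply(seq_len(11), function(i) {
    len <- armL[i] + armR[i]
    list(name = sprintf("chr%02d", i), armLeft = armL[i],
         armRight = armR[i], markerPositions = seq(0, len, by = spacing))
  })
  if (is.null(qtls)) {
    qtls <- data.frame(
      parent = c("female", "female", "male"),
      chromosome = c("chr02", "chr08", "chr07"),
      position = c(19, 55, 60),
      additive = c(1.0, 0.25, 0.25)
    )
  } else if (length(qtls) == 1 && is.na(qtls[1])) {
    qtls <- NULL
  }
  simConfig(
    nIndividuals = nIndividuals, chromosomes = chroms,
    snpTypeMix = c(I = 1954, II = 702, III = 2537, IV = 2338, V = 2468) /
      9999,
    translocation = if (translocation) c("chr09", "chr10") else NULL,
    qtls = qtls, traitMean = 4.5, residualSd = 1.046,
    seed = seed, ...
  )
}

#' Build the phased meiosis model of one parent
#'
#' Assembles the per-chromosome phased loci (testcross markers of this
#' parent plus this parent's QTL as pseudo-loci) used by
#' [simulateGamete()]. Phases (which homolog carries the "a" allele) are
#' drawn from the current RNG stream; QTL "+" alleles sit on homolog 1.
#' For a translocation heterozygote, homolog 1 of each involved arm is the
#' copy residing on the normal (non-translocated) chromosome.
#'
#' @param config a `SimConfig`.
#' @param parent `"female"` or `"male"`.
#' @return a parent model list (chromosome loci, phases, translocation).
#' @export
parentModel <- function(config, parent = c("female", "male")) {
  parent <- match.arg(parent)
  trans <- if (parent == "female") config$translocation else NULL
  qtls <- config$qtls
  chroms <- lapply(config$chromosomes, function(ch) {
    pos <- ch$markerPositions
    ids <- sprintf("%s_%s_%05.1f", toupper(substr(parent, 1, 1)),
                   ch$name, pos)
    phase <- sample(c(1L, 2L), length(pos), replace = TRUE)
    qpos <- qname <- NULL
    if (!is.null(qtls)) {
      qi <- which(qtls$parent == parent & qtls$chromosome == ch$name)
      if (length(qi)) {
        qpos <- qtls$position[qi]
        qname <- sprintf("QTL_%s_%g", ch$name, qpos)
      }
    }
    list(name = ch$name, armLeft = ch$armLeft, armRight = ch$armRight,
         positions = c(pos, qpos),
         loci = c(ids, qname),
         phase = c(phase, rep(1L, length(qpos))),
         isQtl = c(rep(FALSE, length(pos)), rep(TRUE, length(qpos))))
  })
  names(chroms) <- vapply(config$chromosomes, `[[`, character(1), "name")
  list(parent = parent, chromosomes = chroms, translocation = trans)
}

# Copy indicator (1 or 2) transmitted at each locus of one arm, walking
# outward from the junction: `start` copy flips at each Haldane (Poisson,
# rate 1/100 per cM) crossover.
.armCopies <- function(start, distances, armLength) {
  if (!length(distances)) return(integer())
  ncx <- stats::rpois(1L, armLength / 100)
  if (ncx == 0) return(rep(start, length(distances)))
  cx <- sort(stats::runif(ncx, 0, armLength))
  flips <- findInterval(distances, cx)
  1L + (start - 1L + flips) %% 2L
}

#' Simulate one gamete of a parent
#'
#' Meiosis with Haldane (no-interference Poisson) crossovers per
#' chromosome arm. For a reciprocal-translocation heterozygote only
#' alternate segregation is modelled: a fair coin transmits either the two
#' normal chromosomes or the two translocated ones (balanced gametes;
#' adjacent segregation products, which carry duplications/deficiencies
#' and abort, are never emitted). Draws come from the current RNG stream.
#'
#' @param model a parent model from [parentModel()].
#' @return list with `copies` (named integer vector over all loci; 1 =
#'   homolog-1/normal-chromosome copy, 2 = the other) and `arrangement`
#'   (`"normal"`, `"translocated"`, or `NA` without a translocation).
#' @export
simulateGamete <- function(model) {
  trans <- model$translocation
  arrangement <- NA_character_
  transStart <- NA_integer_
  if (!is.null(trans)) {
    transStart <- sample(c(1L, 2L), 1L)
    arrangement <- c("normal", "translocated")[transStart]
  }
  copies <- lapply(model$chromosomes, function(ch) {
    pos <- ch$positions
    out <- integer(length(pos))
    j <- ch$armLeft
    left <- pos <= j
    if (!is.null(trans) && ch$name %in% trans) {
      startL <- startR <- transStart
    } else {
      # independent centromere coin per non-translocated chromosome
      startL <- startR <- sample(c(1L, 2L), 1L)
    }
    out[left] <- .armCopies(startL, j - pos[left], ch$armLeft)
    out[!left] <- .armCopies(startR, pos[!left] - j, ch$armRight)
    names(out) <- ch$loci
    out
  })
  list(copies = unlist(unname(copies)), arrangement = arrangement)
}

# SNP-type template parent genotypes (nucleotide coding for metadata).
.TYPE_PARENTS <- list(
  I   = c(female = "AA", male = "AA"),
  II  = c(female = "AA", male = "GG"),
  III = c(female = "AG", male = "AG"),
  IV  = c(female = "AG", male = "AA"),
  V   = c(female = "AA", male = "AG")
)

#' Simulate a complete F1 pseudo-testcross population
#'
#' Runs [simulateGamete()] for both parents of every individual, emits the
#' testcross-coded genotype matrix (calls are the transmitted allele of
#' the informative parent), the trait table from the planted-QTL additive
#' model, and a ground-truth record filled before genotyping noise is
#' applied. Draw order is fixed: marker phases (female model, then male),
#' then per individual the female gamete and the male gamete chromosome by
#' chromosome, then residuals per year, then missing-call and allele-flip
#' noise — so equal seeds give identical output.
#'
#' @param config a `SimConfig`.
#' @return list with elements `genotypes` ([TestcrossGenotypes-class]),
#'   `traits` (data.frame `individual`, `year`, `trait`) and `truth`
#'   (list: `arrangement` per individual, `qtlAlleles` matrix of +/-1,
#'   `breakpoints`, `phases`, `femaleMap`/`maleMap` true marker
#'   positions).
#' @examples
#' cfg <- defaultSimConfig(nIndividuals = 20, spacing = 20, seed = 7)
#' pop <- simulatePopulation(cfg)
#' pop$genotypes
#' @export
simulatePopulation <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n <- config$nIndividuals
  indIds <- sprintf("F1_%03d", seq_len(n))

  fm <- parentModel(config, "female")
  mm <- parentModel(config, "male")

  fLoci <- unlist(lapply(fm$chromosomes, `[[`, "loci"), use.names = FALSE)
  fIsQtl <- unlist(lapply(fm$chromosomes, `[[`, "isQtl"), use.names = FALSE)
  fPhase <- unlist(lapply(fm$chromosomes, `[[`, "phase"), use.names = FALSE)
  mLoci <- unlist(lapply(mm$chromosomes, `[[`, "loci"), use.names = FALSE)
  mIsQtl <- unlist(lapply(mm$chromosomes, `[[`, "isQtl"), use.names = FALSE)
  mPhase <- unlist(lapply(mm$chromosomes, `[[`, "phase"), use.names = FALSE)

  fCopies <- matrix(0L, length(fLoci), n, dimnames = list(fLoci, indIds))
  mCopies <- matrix(0L, length(mLoci), n, dimnames = list(mLoci, indIds))
  arrangement <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    g <- simulateGamete(fm)
    fCopies[, i] <- g$copies
    arrangement[i] <- g$arrangement
    mCopies[, i] <- simulateGamete(mm)$copies
  }

  # testcross calls: 'a' when the transmitted copy matches the phase
  fCalls <- ifelse(fCopies[!fIsQtl, , drop = FALSE] ==
                     fPhase[!fIsQtl], "a", "b")
  mCalls <- ifelse(mCopies[!mIsQtl, , drop = FALSE] ==
                     mPhase[!mIsQtl], "a", "b")

  chrOf <- function(model, isQtl) {
    rep(names(model$chromosomes),
        vapply(model$chromosomes, function(ch) length(ch$loci),
               integer(1)))[!isQtl]
  }
  posOf <- function(model, isQtl) {
    unlist(lapply(model$chromosomes, `[[`, "positions"),
           use.names = FALSE)[!isQtl]
  }
  fChr <- chrOf(fm, fIsQtl); fPos <- posOf(fm, fIsQtl)
  mChr <- chrOf(mm, mIsQtl); mPos <- posOf(mm, mIsQtl)

  # one scaffold per (chromosome, position); both parents' markers at a
  # position share it, anchoring the two maps
  scafOf <- function(chr, pos) sprintf("Sc.SIM_%s_%04.0f", chr, pos * 10)
  markerId <- function(chr, pos, parent)
    sprintf("Sc.SIM_%s_%04.0f_%s", chr, pos * 10, parent)
  fIds <- markerId(fChr, fPos, "F")
  mIds <- markerId(mChr, mPos, "M")
  rownames(fCalls) <- fIds
  rownames(mCalls) <- mIds

  testInfo <- data.frame(
    scaffold = c(scafOf(fChr, fPos), scafOf(mChr, mPos)),
    position = as.integer(round(c(fPos, mPos) * 10) + 1L),
    snpType = rep(c("IV", "V"), c(length(fIds), length(mIds))),
    segregatingParent = rep(c("female", "male"),
                            c(length(fIds), length(mIds))),
    parentFemale = rep(c("AG", "AA"), c(length(fIds), length(mIds))),
    parentMale = rep(c("AA", "AG"), c(length(fIds), length(mIds))),
    source = "SNP",
    chromosome = c(fChr, mChr), cm = c(fPos, mPos),
    row.names = c(fIds, mIds)
  )
  callsMat <- rbind(fCalls, mCalls)

  # non-testcross filler loci per snpTypeMix (anchored on the IV share)
  mix <- config$snpTypeMix
  nIV <- length(fIds)
  filler <- NULL
  if (mix[["IV"]] > 0) {
    for (tp in c("I", "II", "III")) {
      nt <- round(nIV * mix[[tp]] / mix[["IV"]])
      if (nt < 1) next
      ids <- sprintf("Sc.FIL_%s_%05d_1", tp, seq_len(nt))
      callsT <- matrix(if (tp == "III") NA_character_ else "a",
                       nt, n, dimnames = list(ids, indIds))
      infoT <- data.frame(
        scaffold = sprintf("Sc.FIL_%s_%05d", tp, seq_len(nt)),
        position = 1L, snpType = tp,
        segregatingParent = if (tp == "III") "both" else "none",
        parentFemale = .TYPE_PARENTS[[tp]][["female"]],
        parentMale = .TYPE_PARENTS[[tp]][["male"]],
        source = "SNP", chromosome = NA_character_, cm = NA_real_,
        row.names = ids
      )
      filler <- list(calls = rbind(filler$calls, callsT),
                     info = rbind(filler$info, infoT))
    }
  }
  if (!is.null(filler)) {
    callsMat <- rbind(callsMat, filler$calls)
    testInfo <- rbind(testInfo, filler$info)
  }

  # trait model: transmitted QTL allele contributes +/- additive
  qtlAlleles <- NULL
  genetic <- rep(0, n)
  if (!is.null(config$qtls)) {
    qn <- sprintf("QTL_%s_%g", config$qtls$chromosome, config$qtls$position)
    qtlAlleles <- matrix(0L, length(qn), n, dimnames = list(qn, indIds))
    for (k in seq_along(qn)) {
      src <- if (config$qtls$parent[k] == "female") fCopies else mCopies
      qtlAlleles[k, ] <- ifelse(src[qn[k], ] == 1L, 1L, -1L)
      genetic <- genetic + config$qtls$additive[k] * qtlAlleles[k, ]
    }
  }
  traits <- do.call(rbind, lapply(seq_len(config$years), function(y) {
    tr <- config$traitMean + genetic +
      stats::rnorm(n, 0, config$residualSd)
    data.frame(individual = indIds, year = y, trait = tr)
  }))
  if (config$ratingScale) {
    rng <- range(traits$trait)
    traits$trait <- pmin(9L, 1L + as.integer(
      floor(9 * (traits$trait - rng[1]) / (rng[2] - rng[1]))))
  }

  truth <- list(
    arrangement = stats::setNames(arrangement, indIds),
    qtlAlleles = qtlAlleles,
    qtls = config$qtls,
    breakpoints = if (is.null(config$translocation)) NULL else {
      chrs <- config$translocation
      data.frame(chromosome = chrs,
                 junction = vapply(chrs, function(cn)
                   fm$chromosomes[[cn]]$armLeft, numeric(1)))
    },
    phases = list(
      female = stats::setNames(fPhase[!fIsQtl], fIds),
      male = stats::setNames(mPhase[!mIsQtl], mIds)
    ),
    femaleMap = data.frame(marker = fIds, chromosome = fChr, cm = fPos),
    maleMap = data.frame(marker = mIds, chromosome = mChr, cm = mPos)
  )

  geno <- TestcrossGenotypes(callsMat, testInfo)
  geno <- applyGenotypingNoise(geno, config$missingRate, config$errorRate)
  list(genotypes = geno, traits = traits, truth = truth)
}

#' Inject GBS-style genotyping noise
#'
#' Independently sets each call missing with probability `missingRate`,
#' then flips each surviving call a<->b with probability `errorRate`.
#' Marker metadata is untouched. Uses the current RNG stream.
#'
#' @param x a [TestcrossGenotypes-class].
#' @param missingRate,errorRate rates in `[0, 1)`.
#' @return the noised [TestcrossGenotypes-class].
#' @export
applyGenotypingNoise <- function(x, missingRate, errorRate) {
  if (missingRate < 0 || missingRate >= 1 || errorRate < 0 || errorRate >= 1)
    stop("rates must lie in [0, 1)")
  if (missingRate == 0 && errorRate == 0) return(x)
  cl <- calls(x)
  nc <- length(cl)
  if (missingRate > 0)
    cl[stats::runif(nc) < missingRate] <- NA_character_
  if (errorRate > 0) {
    flip <- !is.na(cl) & stats::runif(nc) < errorRate
    cl[flip] <- ifelse(cl[flip] == "a", "b", "a")
  }
  SummarizedExperiment::assay(x, "calls") <- cl
  x
}
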