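#' Classify a biallelic SNP by parental state
#'
#' Assigns one of the five parental-state SNP types of a full-sib cross
#' and its expected progeny segregation: I both parents homozygous for the
#' same allele (not segregating, all progeny homozygous); II both parents
#' homozygous for different alleles (not segregating, all progeny
#' heterozygous); III both heterozygous (1:2:1, excluded from testcross
#' mapping because its recombination estimate mixes both meioses); IV only
#' the female heterozygous (1:1, female-informative testcross); V only the
#' male heterozygous (1:1, male-informative testcross).
#'
#' @param gFemale,gMale diploid genotypes as two-character strings, e.g.
#'   `"AG"` (allele order irrelevant).
#' @return list with `snpType`, `segregation`, `segregatingParent` and
#'   `testcross` (logical: usable for pseudo-testcross mapping).
#' @examples
#' classifySnpType("AG", "AA")  # type IV, 1:1, female-informative
#' @export
classifySnpType <- function(gFemale, gMale) {
  alleles <- function(g) {
    if (!is.character(g) || length(g) != 1 || nchar(g) != 2)
      stop("genotype must be a two-letter string")
    sort(strsplit(g, "")[[1]])
  }
  af <- alleles(gFemale); am <- alleles(gMale)
  if (length(unique(c(af, am))) > 2)
    stop("unsupported site: more than two alleles across parents")
  hf <- af[1] != af[2]; hm <- am[1] != am[2]
  if (!hf && !hm) {
    if (af[1] == am[1])
      return(list(snpType = "I",
                  segregation = "not segregating (all progeny homozygous)",
                  segregatingParent = "none", testcross = FALSE))
    return(list(snpType = "II",
                segregation = "not segregating (all progeny heterozygous)",
                segregatingParent = "none", testcross = FALSE))
  }
  if (hf && hm)
    return(list(snpType = "III", segregation = "1:2:1",
                segregatingParent = "both", testcross = FALSE))
  if (hf)
    return(list(snpType = "IV", segregation = "1:1",
                segregatingParent = "female", testcross = TRUE))
  list(snpType = "V", segregation = "1:1",
       segregatingParent = "male", testcross = TRUE)
}

# 1-df chi-square quantiles bounding the distortion tiers
.CHI2_TIERS <- c(alpha10 = stats::qchisq(0.90, 1),
                 alpha05 = stats::qchisq(0.95, 1),
                 alpha01 = stats::qchisq(0.99, 1))

#' Test 1:1 segregation of a testcross marker
#'
#' Pearson chi-square against the expected 1:1 ratio (no continuity
#' correction), with the three-tier distortion classification used for
#' map construction: `normal` when chi2 <= the alpha=0.1 quantile (2.706);
#' one asterisk up to the alpha=0.05 quantile (3.841); two asterisks up to
#' the alpha=0.01 quantile (6.635); `excluded` beyond that.
#'
#' @param countA,countB observed counts of the two call classes.
#' @return list with `chi2`, `p`, `class` in
#'   `c("normal", "*", "**", "excluded")`.
#' @examples
#' segregationTest(60, 40)  # chi2 = 4, class "**"
#' @export
segregationTest <- function(countA, countB) {
  if (countA < 0 || countB < 0) stop("counts must be nonnegative")
  n <- countA + countB
  if (n == 0) stop("undefined test: both counts are zero")
  e <- n / 2
  chi2 <- (countA - e)^2 / e + (countB - e)^2 / e
  class <- if (chi2 <= .CHI2_TIERS[["alpha10"]]) "normal"
    else if (chi2 <= .CHI2_TIERS[["alpha05"]]) "*"
    else if (chi2 <= .CHI2_TIERS[["alpha01"]]) "**"
    else "excluded"
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
       class = class)
}

#' Segregation distortion classes for all markers of one parent
#'
#' @param x a [TestcrossGenotypes-class].
#' @return data.frame `marker`, `countA`, `countB`, `chi2`, `class`.
#' @export
segregationClasses <- function(x) {
  cl <- calls(x)
  a <- rowSums(cl == "a", na.rm = TRUE)
  b <- rowSums(cl == "b", na.rm = TRUE)
  n <- a + b
  chi2 <- ifelse(n > 0, (a - b)^2 / n, NA_real_)
  class <- as.character(cut(chi2,
    c(-Inf, .CHI2_TIERS[["alpha10"]], .CHI2_TIERS[["alpha05"]],
      .CHI2_TIERS[["alpha01"]], Inf),
    labels = c("normal", "*", "**", "excluded")))
  data.frame(marker = rownames(cl), countA = a, countB = b,
             chi2 = chi2, class = class, row.names = NULL)
}

#' Find markers with identical segregation patterns
#'
#' Two markers are redundant when their calls agree at every
#' pairwise-complete individual (similarity 1.000) over at least
#' `minOverlap` shared non-missing calls. Redundant markers are clustered
#' transitively; each cluster keeps one representative (fewest missing
#' calls, ties by lexicographic marker id).
#'
#' @param x a [TestcrossGenotypes-class].
#' @param minOverlap minimum shared non-missing calls (default 30).
#' @param matchComplement also treat perfectly complementary columns
#'   (identical after an a<->b swap, i.e. the same locus scored in the
#'   opposite phase) as redundant (default FALSE).
#' @return list with `clusters` (list of marker-id vectors, size >= 2),
#'   `representatives` (one id per cluster) and `redundant` (ids to drop).
#' @export
findRedundantMarkers <- function(x, minOverlap = 30,
                                 matchComplement = FALSE) {
  cl <- calls(x)
  p <- nrow(cl)
  if (p < 2)
    return(list(clusters = list(), representatives = character(),
                redundant = character()))
  if (!anyNA(cl) && ncol(cl) >= minOverlap && !matchComplement) {
    # complete data: identity on pairwise-complete calls is plain
    # column identity, found by hashing
    key <- apply(cl, 1, paste, collapse = "")
    clusters <- split(rownames(cl), key)
    clusters <- unname(clusters[lengths(clusters) >= 2])
    clusters <- lapply(clusters, sort)
    reps <- vapply(clusters, `[`, character(1), 1)
    return(list(clusters = clusters, representatives = reps,
                redundant = setdiff(unlist(clusters), reps)))
  }
  X <- matrix(0, p, ncol(cl)); X[cl == "b"] <- 1   # a=0, b=1
  M <- !is.na(cl)
  X[!M] <- 0
  Cm <- M * 1
  nShared <- tcrossprod(Cm)
  half <- tcrossprod(X, Cm - X)
  mismatch <- half + t(half)
  same <- mismatch == 0 & nShared >= minOverlap
  if (matchComplement)
    same <- same | (mismatch == nShared & nShared >= minOverlap)
  same[lower.tri(same, diag = TRUE)] <- FALSE
  edges <- which(same, arr.ind = TRUE, useNames = FALSE)
  if (!nrow(edges))
    return(list(clusters = list(), representatives = character(),
                redundant = character()))
  g <- igraph::make_empty_graph(n = p, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  names(comp) <- rownames(cl)
  nMissing <- rowSums(!M)
  clusters <- split(names(comp), comp)
  clusters <- clusters[lengths(clusters) >= 2]
  reps <- vapply(clusters, function(ids) {
    ids[order(nMissing[ids], ids)][1]
  }, character(1))
  list(clusters = unname(clusters), representatives = unname(reps),
       redundant = setdiff(unlist(clusters), reps))
}

#' Select one framework marker per scaffold
#'
#' Keeps a single marker per genome scaffold for framework map
#' construction (the rest become accessory markers): the marker with the
#' fewest missing calls, ties broken by lowest bp position, then by
#' lexicographic id.
#'
#' @param x a [TestcrossGenotypes-class].
#' @return list with `framework` and `accessory` marker-id vectors.
#' @export
selectFramework <- function(x) {
  info <- markerInfo(x)
  nMissing <- rowSums(is.na(calls(x)))
  ids <- rownames(x)
  o <- order(info$scaffold, nMissing, info$position, ids)
  best <- o[!duplicated(info$scaffold[o])]
  keep <- logical(length(ids)); keep[best] <- TRUE
  list(framework = ids[keep], accessory = ids[!keep])
}

#' Run the full marker QC funnel for one parent
#'
#' Restricts to testcross markers of the given parent, excludes
#' significantly distorted markers (chi2 beyond the alpha=0.01 tier),
#' removes redundant markers, and splits the rest into framework and
#' accessory sets; the funnel counts (input = retained + distorted +
#' redundant + accessory) are recorded on the returned object.
#'
#' @param x a [TestcrossGenotypes-class].
#' @param parent `"female"` or `"male"`.
#' @param minOverlap passed to [findRedundantMarkers()].
#' @return list with `genotypes` (framework [TestcrossGenotypes-class]
#'   carrying the funnel), `distortion` (the [segregationClasses()] table
#'   of the retained framework markers), `excluded`, `redundant`,
#'   `accessory` id vectors.
#' @export
markerQc <- function(x, parent = c("female", "male"), minOverlap = 30) {
  parent <- match.arg(parent)
  xs <- x[markerInfo(x)$segregatingParent == parent &
            markerInfo(x)$snpType %in% c("IV", "V"), ]
  nInput <- nrow(xs)
  seg <- segregationClasses(xs)
  excluded <- seg$marker[!is.na(seg$class) & seg$class == "excluded"]
  keep1 <- setdiff(rownames(xs), excluded)
  red <- findRedundantMarkers(xs[keep1, ], minOverlap = minOverlap)
  fw <- selectFramework(xs[setdiff(keep1, red$redundant), ])
  xf <- xs[fw$framework, ]
  funnel <- c(input = nInput, distorted = length(excluded),
              redundant = length(red$redundant),
              accessory = length(fw$accessory),
              retained = length(fw$framework))
  xf@funnel <- stats::setNames(as.integer(funnel), names(funnel))
  list(genotypes = xf,
       distortion = seg[match(fw$framework, seg$marker), , drop = FALSE],
       excluded = excluded, redundant = red$redundant,
       accessory = fw$accessory)
}
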