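#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.CALL_LEVELS <- c("a", "b")

#' TestcrossGenotypes: testcross-coded marker calls for an F1 population
#'
#' Container for pseudo-testcross genotype data: a markers-by-individuals
#' character matrix of calls in \{"a", "b", NA\} together with per-marker
#' metadata (scaffold of origin, physical position, SNP type I-V,
#' segregating parent, marker source). Extends
#' [SummarizedExperiment::SummarizedExperiment] so that standard subsetting
#' by marker and individual, `rowData()` and `colnames()` semantics apply.
#'
#' The five SNP types follow the parental-state catalogue used for GBS
#' markers in a full-sib cross: I both parents homozygous monomorphic,
#' II both homozygous polymorphic, III both heterozygous (1:2:1, not used
#' for testcross mapping), IV only the female parent heterozygous (1:1),
#' V only the male parent heterozygous (1:1). Only types IV and V are
#' testcross-informative; their calls code the transmitted allele of the
#' heterozygous parent.
#'
#' @slot funnel integer vector of marker counts per filtering class,
#'   maintained by the QC operations (see [markerFunnel()]).
#' @export
setClass("TestcrossGenotypes",
  contains = "SummarizedExperiment",
  representation(funnel = "integer")
)

.validTestcrossGenotypes <- function(object) {
  msg <- NULL
  if (!("calls" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'calls' is required")
  else {
    cl <- SummarizedExperiment::assay(object, "calls")
    if (!is.character(cl))
      msg <- c(msg, "assay 'calls' must be a character matrix")
    else if (!all(cl[!is.na(cl)] %in% .CALL_LEVELS))
      msg <- c(msg, "calls must be 'a', 'b' or NA")
  }
  needed <- c("scaffold", "position", "snpType", "segregatingParent")
  missing <- setdiff(needed, colnames(SummarizedExperiment::rowData(object)))
  if (length(missing))
    msg <- c(msg, paste0("rowData lacks column(s): ",
                         paste(missing, collapse = ", ")))
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "marker ids (rownames) must be present and unique")
  if (is.null(msg)) TRUE else msg
}
setValidity("TestcrossGenotypes", .validTestcrossGenotypes)

#' Construct a TestcrossGenotypes object
#'
#' @param calls character matrix, markers in rows (rownames = marker ids),
#'   individuals in columns; values in \{"a","b",NA\}, with `"-"` accepted
#'   and converted to `NA`.
#' @param markerInfo data.frame or DataFrame with one row per marker and at
#'   least columns `scaffold`, `position` (bp, 1-based), `snpType`
#'   (`"I"`..`"V"`), `segregatingParent` (`"female"`, `"male"`, `"both"`,
#'   `"none"`). An optional `source` column (`"SNP"`/`"SSR"`) defaults to
#'   `"SNP"`.
#' @param funnel optional named integer vector of QC funnel counts.
#' @return a [TestcrossGenotypes-class] object.
#' @examples
#' calls <- matrix(c("a", "b", "a", "b"), nrow = 2,
#'                 dimnames = list(c("m1", "m2"), c("i1", "i2")))
#' info <- data.frame(scaffold = c("s1", "s2"), position = c(10L, 20L),
#'                    snpType = "IV", segregatingParent = "female")
#' tg <- TestcrossGenotypes(calls, info)
#' nMarkers(tg)
#' @export
TestcrossGenotypes <- function(calls, markerInfo, funnel = integer()) {
  calls[calls == "-"] <- NA_character_
  markerInfo <- S4Vectors::DataFrame(markerInfo)
  if (is.null(markerInfo$source)) markerInfo$source <- "SNP"
  if (is.null(rownames(calls)) && !is.null(rownames(markerInfo)))
    rownames(calls) <- rownames(markerInfo)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(calls = calls),
    rowData = markerInfo
  )
  new("TestcrossGenotypes", se, funnel = as.integer(funnel))
}

#' GeneticMap: ordered linkage groups with cM positions
#'
#' A genetic map as a table of markers assigned to named linkage groups,
#' ordered within group, with cumulative Kosambi cM positions starting at 0
#' and per-marker segregation-distortion annotations ("" / "*" / "**").
#'
#' @slot table data.frame with columns `group`, `marker`, `position`
#'   (cM), `asterisks`, and optionally `phase` and `scaffold`.
#' @export
setClass("GeneticMap", representation(table = "data.frame"))

.validGeneticMap <- function(object) {
  tb <- object@table
  msg <- NULL
  need <- c("group", "marker", "position", "asterisks")
  if (!all(need %in% colnames(tb)))
    return(paste("map table needs columns", paste(need, collapse = ", ")))
  bad <- vapply(split(tb$position, tb$group),
                function(p) is.unsorted(p, strictly = FALSE), logical(1))
  if (any(bad))
    msg <- c(msg, "positions must be nondecreasing within each group")
  if (anyDuplicated(tb$marker))
    msg <- c(msg, "a marker may appear only once on the map")
  if (is.null(msg)) TRUE else msg
}
setValidity("GeneticMap", .validGeneticMap)

#' @rdname GeneticMap-class
#' @param table data.frame as described in the class slots.
#' @export
GeneticMap <- function(table) {
  if (is.null(table$asterisks)) table$asterisks <- ""
  new("GeneticMap", table = as.data.frame(table))
}

#' BreakpointCall: localized reciprocal-translocation breakpoints
#'
#' The cross-group marker pair with minimal recombination fraction among the
#' entangled markers, interpreted as flanking the two translocation
#' breakpoints, with their positions on the reference (non-carrier parent)
#' map.
#'
#' @slot markerA,markerB marker ids of the minimum-r pair (one per
#'   reference group).
#' @slot groupA,groupB reference linkage-group names.
#' @slot positionA,positionB cM positions of the pair on the reference map.
#' @slot rhat minimum recombination fraction.
#' @slot nInformative number of pairwise-complete individuals behind rhat.
#' @export
setClass("BreakpointCall", representation(
  markerA = "character", markerB = "character",
  groupA = "character", groupB = "character",
  positionA = "numeric", positionB = "numeric",
  rhat = "numeric", nInformative = "integer"
))

#' SubpopAssignment: arrangement label per F1 individual
#'
#' Per-individual transmitted-arrangement labels around a reciprocal
#' translocation: `"translocated"` (carrier-parent arrangement),
#' `"normal"` (non-carrier arrangement) or `"discarded"` (conflicting or
#' missing breakpoint-proximal evidence, with a recorded reason).
#'
#' @slot assignments data.frame with columns `individual`, `label`,
#'   `reason`.
#' @export
setClass("SubpopAssignment", representation(assignments = "data.frame"))

setValidity("SubpopAssignment", function(object) {
  a <- object@assignments
  if (!all(c("individual", "label", "reason") %in% colnames(a)))
    return("assignments needs columns individual, label, reason")
  if (!all(a$label %in% c("translocated", "normal", "discarded")))
    return("labels must be translocated/normal/discarded")
  if (any(a$label == "discarded" & (is.na(a$reason) | a$reason == "")))
    return("discarded individuals must carry a reason")
  TRUE
})

#' ArmSet: the four chromosome arms rebuilt from an entangled group
#'
#' Marker memberships of the four reconstructed arms of the two
#' linkage groups involved in a reciprocal translocation, named
#' `<LG>a`/`<LG>b` per involved reference group.
#'
#' @slot arms named list of four character vectors (marker ids).
#' @slot dropped character vector of markers discarded near the breakpoints.
#' @export
setClass("ArmSet", representation(arms = "list", dropped = "character"))

setValidity("ArmSet", function(object) {
  ids <- unlist(object@arms, use.names = FALSE)
  if (anyDuplicated(ids)) return("arm marker sets must be pairwise disjoint")
  if (length(object@arms) && is.null(names(object@arms)))
    return("arms must be named")
  TRUE
})
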