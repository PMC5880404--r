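#' @importFrom SummarizedExperiment assay rowData assayNames
NULL

#' @rdname accessors
#' @export
setMethod("calls", "TestcrossGenotypes",
          function(x) assay(x, "calls"))

#' @rdname accessors
#' @export
setMethod("markerInfo", "TestcrossGenotypes",
          function(x) rowData(x))

#' @rdname accessors
#' @export
setMethod("individuals", "TestcrossGenotypes", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("nMarkers", "TestcrossGenotypes", function(x) nrow(x))

#' @rdname accessors
#' @export
setMethod("nIndividuals", "TestcrossGenotypes", function(x) ncol(x))

#' @rdname accessors
#' @export
setMethod("markerFunnel", "TestcrossGenotypes", function(x) x@funnel)

setMethod("show", "TestcrossGenotypes", function(object) {
  cl <- calls(object)
  miss <- mean(is.na(cl))
  cat("TestcrossGenotypes:", nrow(object), "markers x", ncol(object),
      "individuals\n")
  tp <- table(factor(rowData(object)$snpType,
                     levels = c("I", "II", "III", "IV", "V")))
  cat("  SNP types:", paste(names(tp), tp, sep = "=", collapse = " "), "\n")
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  if (length(object@funnel))
    cat("  funnel:", paste(names(object@funnel), object@funnel,
                           sep = "=", collapse = " "), "\n")
})

#' @rdname accessors
#' @export
setMethod("mapTable", "GeneticMap", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("linkageGroups", "GeneticMap",
          function(x) unique(x@table$group))

#' Per-group map summary statistics
#'
#' For each linkage group: size in cM (position of the last marker, 1
#' decimal), marker count, marker density (size divided by count minus one,
#' 1 decimal) and the number of adjacent intervals strictly greater than
#' `gapThreshold` cM. Single-marker groups get size 0 and density 0 with a
#' warning.
#'
#' @param x a [GeneticMap-class].
#' @return data.frame with columns `group`, `size`, `nMarkers`, `density`,
#'   `gaps`.
#' @rdname accessors
#' @export
setMethod("mapSummary", "GeneticMap", function(x) {
  gapThreshold <- 5
  tb <- x@table
  out <- do.call(rbind, lapply(split(tb, factor(tb$group,
                                                levels = unique(tb$group))),
    function(g) {
      n <- nrow(g)
      if (n < 2) {
        warning("single-marker group '", g$group[1],
                "': size and density reported as 0", call. = FALSE)
        return(data.frame(group = g$group[1], size = 0, nMarkers = n,
                          density = 0, gaps = 0L))
      }
      size <- round(max(g$position), 1)
      data.frame(group = g$group[1], size = size, nMarkers = n,
                 density = round(size / (n - 1), 1),
                 gaps = sum(diff(g$position) > gapThreshold))
    }))
  rownames(out) <- NULL
  out
})

setMethod("show", "GeneticMap", function(object) {
  s <- mapSummary(object)
  cat("GeneticMap:", nrow(s), "linkage groups,",
      nrow(object@table), "markers, total",
      round(sum(s$size), 1), "cM\n")
  print(s, row.names = FALSE)
})

setMethod("show", "BreakpointCall", function(object) {
  cat("BreakpointCall\n")
  cat(sprintf("  %s (%s, %.1f cM) -- %s (%s, %.1f cM)\n",
              object@markerA, object@groupA, object@positionA,
              object@markerB, object@groupB, object@positionB))
  cat(sprintf("  r = %.3f over %d informative individuals\n",
              object@rhat, object@nInformative))
})

#' @rdname accessors
#' @export
setMethod("assignments", "SubpopAssignment", function(x) x@assignments)

setMethod("show", "SubpopAssignment", function(object) {
  tab <- table(object@assignments$label)
  cat("SubpopAssignment:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

#' @rdname accessors
#' @export
setMethod("arms", "ArmSet", function(x) x@arms)

setMethod("show", "ArmSet", function(object) {
  cat("ArmSet:", length(object@arms), "arms\n")
  for (nm in names(object@arms))
    cat(sprintf("  %s: %d markers\n", nm, length(object@arms[[nm]])))
  cat("  dropped near breakpoints:", length(object@dropped), "markers\n")
})
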