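#' Read and write testcross genotype tables
#'
#' Tab-delimited dialect: optional `#` comment lines, then a header row
#' `marker  scaffold  position  snpType  segregatingParent  <ind1> ...`,
#' then one row per marker with calls in `a`/`b`/`-`. Write followed by
#' read is the identity.
#'
#' @param path file path.
#' @return [readGenotypes()] returns a [TestcrossGenotypes-class].
#' @export
readGenotypes <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop("empty genotype file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  fixed <- c("marker", "scaffold", "position", "snpType",
             "segregatingParent")
  if (length(header) < 6 || !identical(header[1:5], fixed))
    stop("genotype header must start with: ",
         paste(fixed, collapse = ", "))
  inds <- header[-(1:5)]
  nf <- length(header)
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != nf))
    stop("ragged row at line ", 1 + which(widths != nf)[1] +
           sum(startsWith(sub("\r$", "", readLines(path)), "#")))
  tab <- do.call(rbind, body)
  ids <- tab[, 1]
  if (anyDuplicated(ids))
    stop("duplicate marker id '", ids[duplicated(ids)][1], "' at line ",
         1 + which(duplicated(ids))[1])
  cl <- tab[, -(1:5), drop = FALSE]
  bad <- !(cl %in% c("a", "b", "-"))
  if (any(bad)) {
    k <- arrayInd(which(bad)[1], dim(cl))
    stop("unknown call symbol '", cl[bad][1], "' at line ", 1 + k[1],
         ", individual ", inds[k[2]])
  }
  cl[cl == "-"] <- NA_character_
  dimnames(cl) <- list(ids, inds)
  info <- data.frame(scaffold = tab[, 2],
                     position = as.integer(tab[, 3]),
                     snpType = tab[, 4], segregatingParent = tab[, 5],
                     row.names = ids)
  TestcrossGenotypes(cl, info)
}

#' @rdname readGenotypes
#' @param x a [TestcrossGenotypes-class].
#' @param comments character vector written as leading `#` lines (e.g.
#'   the seed, for provenance).
#' @export
writeGenotypes <- function(x, path, comments = character()) {
  cl <- calls(x)
  cl[is.na(cl)] <- "-"
  info <- markerInfo(x)
  header <- paste(c("marker", "scaffold", "position", "snpType",
                    "segregatingParent", colnames(cl)), collapse = "\t")
  rows <- paste(rownames(cl), info$scaffold, info$position, info$snpType,
                info$segregatingParent,
                apply(cl, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(if (length(comments)) paste("#", comments), header, rows),
             path, useBytes = TRUE)
  invisible(path)
}

#' Read and write trait tables
#'
#' Tab-delimited with header `individual  year  trait`; `#` comment lines
#' allowed.
#'
#' @param path file path.
#' @export
readTraits <- function(path) {
  tb <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("individual", "year", "trait")
  if (!all(need %in% colnames(tb)))
    stop("trait table needs columns ", paste(need, collapse = ", "))
  if (any(!is.finite(tb$trait))) stop("trait values must be finite")
  tb
}

#' @rdname readTraits
#' @param traits data.frame with `individual`, `year`, `trait`.
#' @param comments leading `#` comment lines.
#' @export
writeTraits <- function(traits, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste("#", comments), con)
  utils::write.table(traits, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a genetic map as a tab-delimited table
#'
#' Columns `group`, `marker`, `cM` (1 decimal), `asterisks`, `phase`;
#' [readMap()] parses the table back into a [GeneticMap-class].
#'
#' @param map a [GeneticMap-class].
#' @param path file path.
#' @param comments leading `#` comment lines.
#' @export
writeMap <- function(map, path, comments = character()) {
  tb <- mapTable(map)
  out <- data.frame(group = tb$group, marker = tb$marker,
                    cM = sprintf("%.1f", tb$position),
                    asterisks = tb$asterisks,
                    phase = if (is.null(tb$phase)) "" else tb$phase)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste("#", comments), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeMap
#' @export
readMap <- function(path) {
  tb <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "numeric", "character",
                                         "character"), na.strings = NULL)
  GeneticMap(data.frame(group = tb$group, marker = tb$marker,
                        position = tb$cM, asterisks = tb$asterisks,
                        phase = tb$phase))
}

#' Import testcross markers from a VCF
#'
#' Classifies each biallelic SNP record by the two parents' genotypes
#' ([classifySnpType()]); type IV/V sites are coded to testcross calls by
#' the heterozygous parent's transmitted allele (`"a"` when the
#' transmitted allele is REF), progeny genotypes incompatible with the
#' cross become missing. Non-segregating and intercross (type III) sites,
#' multi-allelic records and indels are skipped and counted.
#'
#' @param path VCF file (plain or bgzipped).
#' @param femaleId,maleId sample ids of the parents.
#' @return list with `genotypes` ([TestcrossGenotypes-class] of the
#'   progeny) and `skipped` (named counts per skip reason).
#' @export
importVcf <- function(path, femaleId, maleId) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (!femaleId %in% samples)
    stop("configuration error: parent sample '", femaleId,
         "' absent from VCF")
  if (!maleId %in% samples)
    stop("configuration error: parent sample '", maleId,
         "' absent from VCF")
  progeny <- setdiff(samples, c(femaleId, maleId))
  fx <- vcfR::getFIX(v)
  skipped <- c(multiallelic = 0L, indel = 0L, nonSegregating = 0L,
               intercross = 0L, missingParent = 0L)
  rows <- list(); info <- list()
  for (i in seq_len(nrow(gt))) {
    ref <- fx[i, "REF"]; alt <- fx[i, "ALT"]
    if (is.na(alt) || grepl(",", alt)) {
      skipped["multiallelic"] <- skipped["multiallelic"] + 1L; next
    }
    if (nchar(ref) != 1 || nchar(alt) != 1) {
      skipped["indel"] <- skipped["indel"] + 1L; next
    }
    toNuc <- function(g) {
      if (is.na(g)) return(NA_character_)
      al <- strsplit(g, "[/|]")[[1]]
      if (length(al) != 2 || any(!al %in% c("0", "1")))
        return(NA_character_)
      paste(ifelse(al == "0", ref, alt), collapse = "")
    }
    gf <- toNuc(gt[i, femaleId]); gm <- toNuc(gt[i, maleId])
    if (is.na(gf) || is.na(gm)) {
      skipped["missingParent"] <- skipped["missingParent"] + 1L; next
    }
    cls <- classifySnpType(gf, gm)
    if (cls$snpType %in% c("I", "II")) {
      skipped["nonSegregating"] <- skipped["nonSegregating"] + 1L; next
    }
    if (cls$snpType == "III") {
      skipped["intercross"] <- skipped["intercross"] + 1L; next
    }
    homAllele <- substr(if (cls$snpType == "IV") gm else gf, 1, 1)
    callOf <- function(g) {
      if (is.na(g)) return(NA_character_)
      al <- strsplit(g, "")[[1]]
      # transmitted-by-het-parent allele: remove one copy of the
      # homozygous parent's allele
      k <- match(homAllele, al)
      if (is.na(k)) return(NA_character_)   # incompatible with cross
      trans <- al[-k]
      if (trans == ref) "a" else "b"
    }
    rows[[length(rows) + 1]] <-
      vapply(gt[i, progeny], function(g) callOf(toNuc(g)),
             character(1))
    info[[length(info) + 1]] <- data.frame(
      marker = sprintf("Sc.AJ_%s_%s", fx[i, "CHROM"], fx[i, "POS"]),
      scaffold = fx[i, "CHROM"], position = as.integer(fx[i, "POS"]),
      snpType = cls$snpType, segregatingParent = cls$segregatingParent)
  }
  if (!length(rows))
    stop("no testcross-informative sites in ", path)
  cl <- do.call(rbind, rows)
  meta <- do.call(rbind, info)
  dimnames(cl) <- list(meta$marker, progeny)
  rownames(meta) <- meta$marker
  list(genotypes = TestcrossGenotypes(cl, meta[, -1, drop = FALSE]),
       skipped = skipped)
}

#' Pipeline configuration
#'
#' Collects every stage parameter with its study-scale default, plus
#' either a simulation block or input file paths. The configuration
#' serialises losslessly to JSON ([readPipelineConfig()] /
#' [writePipelineConfig()]).
#'
#' @param simulate `NULL`, or a list of arguments for
#'   [defaultSimConfig()] (e.g. `nIndividuals`, `spacing`,
#'   `translocation`, `missingRate`, `errorRate`).
#' @param genotypes,traits input file paths (ignored when `simulate` is
#'   given).
#' @param seed integer master seed.
#' @param lodGroup framework grouping LOD (default 12).
#' @param lodArms within-subpopulation grouping LOD (default 4).
#' @param rmax linkage cap on r (default 0.40).
#' @param minBridges pseudo-linkage flag support (default 5).
#' @param rmaxDeclare breakpoint declaration cap (default 0.35).
#' @param windowCm breakpoint conflict window (default 5 cM).
#' @param minOverlap redundancy screen overlap floor (default 30).
#' @param step scan grid step (default 1 cM).
#' @param nPerm permutation count (default 1000).
#' @param alpha genome-wide error rate (default 0.05).
#' @param pKeep cofactor retention p (default 0.02).
#' @param exclusionWindow MQM cofactor exclusion window (default 20 cM).
#' @param stages character vector of stages to run, a subset of
#'   `c("qc", "map", "disentangle", "scan")`.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(simulate = list(), genotypes = NULL,
                           traits = NULL, seed = 1L, lodGroup = 12,
                           lodArms = 4, rmax = 0.40, minBridges = 5,
                           rmaxDeclare = 0.35, windowCm = 5,
                           minOverlap = 30, step = 1, nPerm = 1000,
                           alpha = 0.05, pKeep = 0.02,
                           exclusionWindow = 20,
                           stages = c("qc", "map", "disentangle",
                                      "scan")) {
  stopifnot(all(stages %in% c("qc", "map", "disentangle", "scan")))
  structure(list(simulate = simulate, genotypes = genotypes,
                 traits = traits, seed = as.integer(seed),
                 lodGroup = lodGroup, lodArms = lodArms, rmax = rmax,
                 minBridges = minBridges, rmaxDeclare = rmaxDeclare,
                 windowCm = windowCm, minOverlap = minOverlap,
                 step = step, nPerm = nPerm, alpha = alpha,
                 pKeep = pKeep, exclusionWindow = exclusionWindow,
                 stages = stages), class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param path JSON file path.
#' @export
readPipelineConfig <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipelineConfig, lst)
}

#' @rdname pipelineConfig
#' @param config a `PipelineConfig`.
#' @export
writePipelineConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
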