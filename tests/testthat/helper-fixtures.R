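# shared fixtures, built once per test run

# tiny two-chromosome cross without translocation
tinyConfig <- function(n = 60, spacing = 10, seed = 42, ...) {
  chroms <- list(
    list(name = "chrA", armLeft = 25, armRight = 25,
         markerPositions = seq(0, 50, by = spacing)),
    list(name = "chrB", armLeft = 20, armRight = 20,
         markerPositions = seq(0, 40, by = spacing))
  )
  simConfig(n, chroms,
            snpTypeMix = c(I = 0, II = 0, III = 0, IV = 0.5, V = 0.5),
            seed = seed, ...)
}

# deterministic testcross matrix from explicit call strings
callsFixture <- function(rows, inds = NULL) {
  cl <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  cl[cl == "-"] <- NA_character_
  rownames(cl) <- names(rows)
  colnames(cl) <- if (is.null(inds))
    sprintf("i%02d", seq_len(ncol(cl))) else inds
  info <- data.frame(scaffold = paste0("sc", seq_along(rows)),
                     position = seq_along(rows) * 10L,
                     snpType = "IV", segregatingParent = "female",
                     row.names = names(rows))
  TestcrossGenotypes(cl, info)
}

# moderate translocation population shared by transloc/pipeline tests
.fixtureCache <- new.env(parent = emptyenv())
translocPop <- function() {
  if (is.null(.fixtureCache$pop))
    .fixtureCache$pop <- simulatePopulation(
      translocationStudyConfig(nIndividuals = 213, spacing = 2,
                               seed = 2025))
  .fixtureCache$pop
}
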