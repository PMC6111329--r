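# shared fixtures, all generated in code

# planted-truth dataset with partitions and normalization applied
makePlantedSE <- function(seed, nClasses = 6, nReps = 10, nFeatures = 80,
                          nInformative = 8, effectSize = 0.35,
                          noiseSd = 0.05, split = TRUE) {
  set.seed(seed)
  inf <- sort(sample(nFeatures, nInformative))
  sp <- syntheticSpec(nClasses = nClasses, nReps = nReps,
                      nFeatures = nFeatures, informativeIndices = inf,
                      effectSize = effectSize, noiseSd = noiseSd,
                      seed = seed)
  se <- simulateFeatureDataset(sp)
  if (split) {
    se <- splitData(se, seed = seed)
    se <- normalizeSpectra(se)
  }
  se
}

# manual grouping chromosome from a named list id -> member indices
solutionFromGroups <- function(E, groups) {
  a <- integer(E)
  for (id in names(groups)) a[groups[[id]]] <- as.integer(id)
  GroupingSolution(a)
}

# write a 16-bit stereo PCM WAV from two channel vectors (test-only writer,
# independent of the package's mono writer)
writeStereoWav <- function(path, left, right, fs) {
  inter <- as.vector(rbind(as.integer(round(left * 32767)),
                           as.integer(round(right * 32767))))
  dataSize <- 2L * length(inter)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + dataSize), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs) * 4L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, size = 4, endian = "little")
  writeBin(inter, con, size = 2, endian = "little")
}

# invariant checks for a grouping chromosome, without using the class validity
checkSolutionInvariants <- function(sol, control = NULL) {
  a <- assignment(sol)
  g <- grouping(sol)
  ok <- !is.unsorted(g, strictly = TRUE) &&
    all(a[a != 0L] %in% g) &&
    all(g %in% a) &&
    all(g > 0L)
  if (!is.null(control)) {
    sizes <- tabulate(match(a[a != 0L], g), nbins = length(g))
    ok <- ok && all(sizes >= control$groupSize[1]) &&
      all(sizes <= control$groupSize[2])
  }
  ok
}
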