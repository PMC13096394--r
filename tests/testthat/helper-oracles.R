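# Shared fixtures and independent brute-force oracles.  Everything here
# recomputes quantities by direct enumeration, deliberately avoiding the
# package's vectorized code paths.

# write a data.frame as CSV and ingest it through the public reader
ingest <- function(df, classColumn = "Outcome", idColumn = "id",
                   bins = 3L, binning = "equal_frequency") {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  utils::write.table(df, f, sep = ",", quote = FALSE, row.names = FALSE)
  tab <- readDescriptorTable(f, classColumn, idColumn)
  scales <- buildScales(tab, numericBins = bins, binning = binning)
  list(table = tab, scales = scales,
       sample = codeObjects(tab, scales))
}

# the four-object toy: one scale F with gradations {x, y}, classes {A, B}
toyFixture <- function() {
  ingest(data.frame(id = c("o1", "o2", "o3", "o4"),
                    Outcome = c("A", "A", "B", "B"),
                    F = c("x", "x", "y", "x")))
}

# brute-force frequency counts by triple loop over objects
bruteCounts <- function(sample) {
  inc <- as.matrix(incidence(sample))
  cls <- as.character(classOf(sample))
  lev <- classLevels(sample)
  out <- matrix(0, ncol(inc), length(lev),
                dimnames = list(colnames(inc), lev))
  for (o in seq_len(nrow(inc)))
    for (i in seq_len(ncol(inc)))
      if (inc[o, i] == 1)
        out[i, cls[o]] <- out[i, cls[o]] + 1
  out
}

# brute-force knowledge value for one cell, straight from the formulas
bruteCell <- function(criterion, counts, nObjPerClass, i, j) {
  Nij <- counts[i, j]
  Ni <- sum(counts[i, ]); Nj <- sum(counts[, j]); N <- sum(counts)
  nObj <- sum(nObjPerClass); nObjJ <- nObjPerClass[j]
  P1ij <- if (Nj == 0) 0 else Nij / Nj
  P2ij <- Nij / nObjJ
  P1i <- if (N == 0) 0 else Ni / N
  P2i <- Ni / nObj
  psi <- 1 / log2(nObj)
  zero <- Nij == 0
  switch(criterion,
    PRC1 = P1ij,
    PRC2 = P2ij,
    INF1 = if (zero) 0 else psi * log2(P2ij / P2i),
    INF2 = if (zero) 0 else psi * log2(P1ij / P1i),
    INF3 = Nij - Ni * Nj / N,
    INF4 = if (zero) 0 else P2ij / P2i - 1,
    INF5 = if (zero) 0 else P1ij / P1i - 1,
    INF6 = P2ij - P2i,
    INF7 = P1ij - P1i)
}

bruteModelMatrix <- function(criterion, counts, nObjPerClass) {
  out <- counts * 0
  for (i in seq_len(nrow(counts)))
    for (j in seq_len(ncol(counts)))
      out[i, j] <- bruteCell(criterion, counts, nObjPerClass, i, j)
  out
}

# Pearson correlation from first principles
bruteCor <- function(x, y) {
  n <- length(x)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (den == 0) 0 else num / den
}

# brute-force percent similarity of one object to every class
bruteSimilarity <- function(L, I, criterion = "correlation") {
  vapply(seq_len(ncol(I)), function(j) {
    if (criterion == "correlation") 100 * bruteCor(I[, j], L)
    else {
      d <- sum(abs(I[, j]))
      if (d == 0) 0 else 100 * sum(I[, j] * L) / d
    }
  }, numeric(1))
}

# random tiny coded sample through the public interface: <= 6 objects,
# 2 classes, text scales with <= 3 gradations
randomTinySample <- function(seed) {
  set.seed(seed)
  n <- sample(2:6, 1)
  df <- data.frame(id = paste0("o", seq_len(n)),
                   Outcome = c("A", "B",
                               sample(c("A", "B"), n - 2, replace = TRUE)),
                   V1 = sample(c("a", "b", "c"), n, replace = TRUE),
                   V2 = sample(c("p", "q"), n, replace = TRUE))
  ingest(df)
}

# mid-sized balanced synthetic screen where both class profiles are
# informative; used for pipeline-level behavioral tests
balancedFixture <- function(seed = 7, n = 400, noise = 0, effect = 3) {
  gen <- generateBioassay(nObjects = n, nNumericScales = 3,
                          nTextScales = 9, activeRate = 0.4,
                          nInformative = 8, effectSize = effect,
                          labelNoiseCount = noise, seed = seed)
  sam <- codeObjects(gen$table, buildScales(gen$table))
  list(gen = gen, sample = sam)
}

# expose the internal probability views for invariant checks
.probViewsForTest <- function(fr) ascvs:::.probViews(fr)
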