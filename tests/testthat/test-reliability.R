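# build a recognition result directly from a similarity matrix and truth
mkResult <- function(S, truth) {
  lev <- colnames(S)
  new("RecognitionResult", similarity = S,
      predicted = factor(lev[max.col(S, ties.method = "first")], levels = lev),
      trueClass = factor(truth, levels = lev),
      criterion = "correlation", modelCriterion = "INF3")
}

test_that("confusion components enumerate object-by-class pairs, crisp and fuzzy", {
  fx <- toyFixture()
  m3 <- buildModel(frequencyMatrix(fx$sample), "INF3")
  cc <- confusionCounts(classifySample(fx$sample, m3))
  # brute enumeration of the 8 pairs: o1,o2 correct on A, o3 correct on B,
  # o4 fires on A (false) and misses B
  expect_equal(cc[c("TP", "FP", "FN", "TN")],
               list(TP = 3, FP = 1, FN = 1, TN = 3))
  expect_equal(cc$TPf, 3)
  expect_equal(cc$FPf, 1)
  expect_equal(cc$FNf, 1)
  expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, cc$nPairs)

  # all-zero similarities: nothing positive, every true pair missed
  S0 <- matrix(0, 3, 2, dimnames = list(NULL, c("A", "B")))
  cc0 <- confusionCounts(mkResult(S0, c("A", "B", "A")))
  expect_equal(cc0[c("TP", "FP", "FN")], list(TP = 0, FP = 0, FN = 3))
  expect_equal(cc0$TPf + cc0$FPf + cc0$FNf, 0)

  # doubling the dataset doubles every count
  S <- matrix(c(40, -10, -40, 10), 2, 2, dimnames = list(NULL, c("A", "B")))
  cc1 <- confusionCounts(mkResult(S, c("A", "B")))
  cc2 <- confusionCounts(mkResult(rbind(S, S), c("A", "B", "A", "B")))
  for (nm in c("TP", "FP", "FN", "TN", "TPf", "FPf", "FNf"))
    expect_equal(cc2[[nm]], 2 * cc1[[nm]], label = nm)
})

test_that("F and L1 follow their closed forms, including degenerate cases", {
  comp <- function(TP = 0, FP = 0, FN = 0, TPf = 0, FPf = 0, FNf = 0)
    list(TP = TP, FP = FP, FN = FN, TN = 0, TPf = TPf, FPf = FPf, FNf = FNf)
  expect_equal(as.numeric(fMeasure(comp(TP = 4))), 1)
  expect_equal(as.numeric(fMeasure(comp(FP = 3, FN = 5))), 0)
  expect_equal(as.numeric(fMeasure(comp(TP = 2, FP = 1, FN = 1))), 2 / 3,
               tolerance = 1e-12)
  und <- fMeasure(comp())
  expect_equal(as.numeric(und), 0)
  expect_true(isTRUE(attr(und, "undefined")))

  # two TPs at S = 50 and nothing else: confident-and-correct-only is perfect
  expect_equal(as.numeric(l1Measure(comp(TPf = 1.0))), 1)
  # one TP at S=10 against one FP at S=90: low-confidence truth is penalized
  expect_equal(as.numeric(l1Measure(comp(TPf = 0.1, FPf = 0.9))),
               2 * 0.1 / (0.2 + 0.9), tolerance = 1e-12)
})

test_that("L1 collapses to F1 at saturated similarities and responds monotonically", {
  set.seed(42)
  for (rep in 1:5) {
    # every decision made at full confidence: the fuzzy weights are the
    # crisp counts (a zero-similarity true pair would count for F1 but
    # carry no fuzzy weight, so saturation means |S| = 100 throughout)
    S <- matrix(sample(c(-100, 100), 12, replace = TRUE), 6, 2,
                dimnames = list(NULL, c("A", "B")))
    res <- mkResult(S, sample(c("A", "B"), 6, replace = TRUE))
    cc <- confusionCounts(res)
    expect_equal(as.numeric(l1Measure(cc)), as.numeric(fMeasure(cc)))
  }
  # raising a TP's similarity never lowers L1; raising an FP's never raises it
  S <- matrix(c(30, -20, 25, -40, -30, 20, -25, 40), 4, 2,
              dimnames = list(NULL, c("A", "B")))
  truth <- c("A", "B", "B", "B")   # object 3 is an FP on A
  base <- as.numeric(l1Measure(confusionCounts(mkResult(S, truth))))
  Sup <- S; Sup[1, 1] <- 90        # strengthen a true positive
  expect_gte(as.numeric(l1Measure(confusionCounts(mkResult(Sup, truth)))), base)
  Sfp <- S; Sfp[3, 1] <- 80        # strengthen a false positive
  expect_lte(as.numeric(l1Measure(confusionCounts(mkResult(Sfp, truth)))), base)
})

test_that("model selection ranks by L1 and an all-zero model never wins", {
  fx <- toyFixture()
  fr <- frequencyMatrix(fx$sample)
  m3 <- buildModel(fr, "INF3")
  zero <- m3
  zero@values[] <- 0
  zero@criterion <- "PRC1"
  rep <- selectBestModel(fx$sample, list(PRC1 = zero, INF3 = m3))
  expect_identical(bestModel(rep), "INF3")
  tab <- reliabilityTable(rep)
  expect_equal(tab$L1[tab$criterion == "PRC1"], 0)
  expect_equal(tab$L1[tab$criterion == "INF3"], 0.75)
  expect_equal(tab$F1[tab$criterion == "INF3"], 0.75)

  f <- tempfile(fileext = ".tsv")
  writeReliabilityTable(rep, f)
  expect_identical(utils::read.table(f, sep = "\t", header = TRUE)$criterion,
                   tab$criterion)
  unlink(f)
})

test_that("on cleaned separable balanced data the selected model is perfectly reliable", {
  fx <- balancedFixture(seed = 11)
  cl <- cleanAndRetrain(fx$sample, threshold = 12, maxPasses = 3)
  expect_false(cl$aborted)
  rep <- selectBestModel(cl$sample, cl$models)
  tab <- reliabilityTable(rep)
  best <- tab[1, ]
  expect_gt(best$L1, 0.99)
  expect_gt(best$accuracy, 99)
  # stable selection across seeds
  picks <- vapply(c(11, 12, 13), function(sd) {
    f <- balancedFixture(seed = sd)
    cl <- cleanAndRetrain(f$sample, threshold = 12, maxPasses = 3)
    bestModel(selectBestModel(cl$sample, cl$models))
  }, character(1))
  expect_equal(length(unique(picks)), 1L)
})
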