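# knowledge model with prescribed per-gradation values: one single-gradation
# text scale per value, class columns +v / -v
mkValueModel <- function(v) {
  n <- length(v)
  nms <- paste0("s", seq_len(n))
  scales <- stats::setNames(lapply(nms, function(nm)
    list(name = nm, kind = "text", levels = "g")), nms)
  ss <- new("ScaleSet",
            classScale = list(name = "Outcome", levels = c("A", "B")),
            scales = scales,
            gradations = data.frame(scale = nms, kind = "text", index = 1L,
                                    label = "g", id = paste0(nms, "::g")))
  new("KnowledgeModel", criterion = "INF3",
      values = matrix(c(v, -v), n, 2,
                      dimnames = list(paste0(nms, "::g"), c("A", "B"))),
      psi = 1, scaleSet = ss, fingerprint = "t")
}

test_that("information portraits rank, truncate, and losslessly reconstruct the model column", {
  fx <- toyFixture()
  m3 <- buildModel(frequencyMatrix(fx$sample), "INF3")
  p <- informationPortrait(m3, "A")
  expect_equal(p$gradation, c("x", "y"))
  expect_equal(p$value, c(0.5, -0.5))
  expect_equal(p$sign, c("contributing", "hindering"))
  expect_equal(nrow(informationPortrait(m3, "A", topK = 1)), 1)
  expect_error(informationPortrait(m3, "C"), "unknown class")
  # lossless view: entries reconstruct the column exactly
  col <- modelValues(m3)[, "A"]
  expect_equal(sort(stats::setNames(p$value, p$id)), sort(col))

  zero <- m3; zero@values[] <- 0
  pz <- informationPortrait(zero, "A")
  expect_equal(pz$gradation, c("x", "y"))  # stable gradation order
  expect_true(all(pz$sign == "neutral"))
})

test_that("significance is the across-class population sd, sorted with a valid Pareto curve", {
  fx <- toyFixture()
  m3 <- buildModel(frequencyMatrix(fx$sample), "INF3")
  sig <- significanceTable(m3)
  # two-class sd of (+0.5, -0.5) is 0.5 for both gradations
  expect_equal(sig@gradations$sigma, c(0.5, 0.5))
  expect_equal(sig@gradations$cumPercent, c(50, 100))

  oneClass <- m3
  oneClass@values <- m3@values[, 1, drop = FALSE]
  expect_error(significanceTable(oneClass), "two class")

  # a single informative gradation: the curve hits 100% at the first feature
  pm <- significanceTable(mkValueModel(c(2, 0, 0, 0)))
  expect_equal(pm@gradations$cumPercent[1], 100)
  expect_equal(paretoCoverage(pm, 0.25, "gradation"), 100)

  # invariant to positive rescaling of the model
  m2 <- mkValueModel(c(3, 2, 1))
  m2s <- m2; m2s@values <- 5 * m2s@values
  expect_equal(significanceTable(m2s)@gradations$cumPercent,
               significanceTable(m2)@gradations$cumPercent)
})

test_that("Pareto coverage interpolates the cumulative significance share", {
  uni <- significanceTable(mkValueModel(rep(1, 10)))
  expect_equal(paretoCoverage(uni, 1), 100)
  expect_equal(paretoCoverage(uni, 0.5), 50)
  expect_equal(paretoCoverage(uni, 0.25, "gradation"), 25)
  geo <- significanceTable(mkValueModel(0.5^(0:7)))
  expect_equal(paretoCoverage(geo, 0.25),
               100 * 1.5 / sum(0.5^(0:7)), tolerance = 1e-9)
  expect_error(paretoCoverage(geo, 0), "featureFraction")
  expect_error(paretoCoverage(geo, 1.2), "featureFraction")
})

test_that("contribution graphs filter ranked signed edges deterministically", {
  fx <- toyFixture()
  m3 <- buildModel(frequencyMatrix(fx$sample), "INF3")
  # filter larger than the edge set: all four edges
  g <- contributionGraph(m3, topK = 14)
  expect_equal(nrow(g), 4)
  expect_setequal(unique(g$sign), c("-", "+"))
  # equal |I| everywhere: top 50% keeps two edges, tie-broken by order
  g2 <- contributionGraph(m3, topPercent = 50)
  expect_equal(nrow(g2), 2)
  expect_equal(g2$id, c("F::x", "F::x"))
  g1 <- contributionGraph(mkValueModel(c(3, 1, 2)), topK = 1)
  expect_equal(g1$scale, "s1")
  expect_equal(g1$weight, 3)
  expect_error(contributionGraph(m3), "exactly one")
  expect_warning(g0 <- contributionGraph(m3, topPercent = 1), "no edges")
  expect_equal(nrow(g0), 0)
  # zero-weight edges never appear
  gz <- contributionGraph(mkValueModel(c(1, 0)), topK = 10)
  expect_true(all(gz$weight != 0))

  f <- tempfile(fileext = ".dot")
  writeGraphDOT(g, f)
  dot <- readLines(f)
  expect_true(any(grepl("color=red", dot)) && any(grepl("color=blue", dot)))
  expect_true(any(grepl("F::x", dot, fixed = TRUE)))
  unlink(f)
})

test_that("imbalance baselines are exact and complementary", {
  b <- baselineStats(3523, 48)
  expect_equal(round(b$prevalencePercent, 1), 1.4)
  expect_equal(round(b$trivialAccuracyPercent, 2), 98.64)
  expect_equal(b$trivialCorrect, 3475)
  expect_identical(b$prevalencePercent + b$trivialAccuracyPercent, 100)
  expect_equal(baselineStats(10, 0),
               list(prevalencePercent = 0, trivialAccuracyPercent = 100,
                    trivialCorrect = 10))
  expect_equal(baselineStats(10, 10)$trivialAccuracyPercent, 0)
  expect_error(baselineStats(0, 0), "positive")
  expect_error(baselineStats(5, 6), "nActive")
})
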