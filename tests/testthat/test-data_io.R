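test_that("reader handles delimiters, ids, trailing blanks, and malformed input", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("id,Outcome,XlogP", "a,Active,1.2", "b,Inactive,3.4"), f)
  tab <- readDescriptorTable(f, "Outcome", "id")
  expect_identical(objectIds(tab), c("a", "b"))
  expect_identical(tab@classLabels, c("Active", "Inactive"))
  expect_identical(names(tab@data), "XlogP")

  # tab-delimited, auto-detected; no id column -> sequential ids
  g <- tempfile(fileext = ".tsv")
  writeLines(c("Outcome\tMW", "Active\t100", "Inactive\t200",
               "Inactive\t300", "", ""), g)
  tg <- readDescriptorTable(g, "Outcome")
  expect_identical(objectIds(tg), c("S1", "S2", "S3"))

  expect_error(readDescriptorTable(f, "Missing"), "class column")
  writeLines(c("id,Outcome,X", "a,Active,1", "a,Inactive,2"), f)
  expect_error(readDescriptorTable(f, "Outcome", "id"), "duplicate")
  writeLines(c("id,Outcome,X", "a,Active,1", "b,Inactive"), f)
  expect_error(readDescriptorTable(f, "Outcome", "id"), "line 3")
  writeLines(c("id,Outcome,X", "a,,1", "b,Inactive,2"), f)
  expect_error(readDescriptorTable(f, "Outcome", "id"), "missing values")
  unlink(c(f, g))
})

test_that("write/read round trip preserves values and column order", {
  df <- data.frame(id = c("a", "b"), Outcome = c("Active", "Inactive"),
                   XlogP = c("1.2", "3.4"), Code = c("NEG_no1_NEG", "x y"))
  f <- tempfile(fileext = ".csv")
  utils::write.table(df, f, sep = ",", quote = FALSE, row.names = FALSE)
  tab <- readDescriptorTable(f, "Outcome", "id")
  g <- tempfile(fileext = ".csv")
  writeDescriptorTable(tab, g)
  expect_identical(readLines(g), readLines(f))
  unlink(c(f, g))
})

test_that("scale building infers kinds, bins numerics, normalizes text", {
  fx <- ingest(data.frame(
    id = paste0("o", 1:4), Outcome = c("A", "A", "B", "B"),
    BBB = c("0", "1", "1", "0"),
    X = c("1.0", "2.0", "3.0", "4.0"),
    Txt = c("NEG_no1_NEG ", "NEG_no1_NEG", " NEG_no1_NEG", "NEG  no1"),
    Mixed = c("1", "2", "x", "3")), bins = 3, binning = "equal_width")
  sc <- fx$scales
  # {0,1} has fewer distinct values than bins: two point gradations
  expect_identical(sc@scales$BBB$kind, "numeric")
  expect_identical(sc@scales$BBB$points, c(0, 1))
  # one stray token turns the whole column into text
  expect_identical(sc@scales$Mixed$kind, "text")
  # whitespace runs collapse: two gradations, not four
  expect_identical(sc@scales$Txt$levels, c("NEG no1", "NEG_no1_NEG"))

  fx2 <- ingest(data.frame(id = paste0("o", 1:4), Outcome = c("A", "A", "B", "B"),
                           X = c("1.0", "2.0", "3.0", "4.0")),
                bins = 2, binning = "equal_width")
  expect_equal(fx2$scales@scales$X$breaks, c(1, 2.5, 4))
  gr <- gradationInfo(fx2$scales)
  expect_identical(gr$label, c("[1,2.5)", "[2.5,4]"))

  # all-missing column dropped with a warning; constant column is one gradation
  df3 <- data.frame(id = paste0("o", 1:3), Outcome = c("A", "B", "B"),
                    Empty = c("", "", ""), Const = c("5", "5", "5"))
  f <- tempfile(fileext = ".csv")
  utils::write.table(df3, f, sep = ",", quote = FALSE, row.names = FALSE)
  tab3 <- readDescriptorTable(f, "Outcome", "id")
  expect_warning(sc3 <- buildScales(tab3), "all-missing")
  expect_false("Empty" %in% names(sc3@scales))
  expect_identical(unname(scaleCounts(sc3)["nGradations"]), 1L)
  unlink(f)
})

test_that("coding sets one bit per observed scale, clamps, and flags unseen values", {
  train <- ingest(data.frame(id = paste0("o", 1:4),
                             Outcome = c("A", "A", "B", "B"),
                             X = c("1.0", "2.0", "3.0", "4.0"),
                             T1 = c("u", "v", "u", "v")),
                  bins = 2, binning = "equal_width")
  # containment: 1.2 falls in [1, 2.5)
  newdf <- data.frame(id = "n1", Outcome = "A", X = "1.2", T1 = "u")
  f <- tempfile(fileext = ".csv")
  utils::write.table(newdf, f, sep = ",", quote = FALSE, row.names = FALSE)
  coded <- codeObjects(readDescriptorTable(f, "Outcome", "id"), train$scales)
  expect_equal(unname(as.matrix(incidence(coded))[1, ]), c(1, 0, 1, 0))

  # out-of-range value clamps to the boundary interval, with a warning
  newdf$X <- "9.9"
  utils::write.table(newdf, f, sep = ",", quote = FALSE, row.names = FALSE)
  expect_warning(
    coded2 <- codeObjects(readDescriptorTable(f, "Outcome", "id"),
                          train$scales),
    "clamped")
  expect_equal(unname(as.matrix(incidence(coded2))[1, 1:2]), c(0, 1))

  # unseen text gradation codes as absent for that scale
  newdf$X <- "1.2"; newdf$T1 <- "w"
  utils::write.table(newdf, f, sep = ",", quote = FALSE, row.names = FALSE)
  expect_warning(
    coded3 <- codeObjects(readDescriptorTable(f, "Outcome", "id"),
                          train$scales),
    "absent")
  expect_equal(sum(as.matrix(incidence(coded3))[1, 3:4]), 0)

  # missing value sets no bit
  newdf$T1 <- ""
  utils::write.table(newdf, f, sep = ",", quote = FALSE, row.names = FALSE)
  coded4 <- codeObjects(readDescriptorTable(f, "Outcome", "id"), train$scales)
  expect_equal(unname(Matrix::rowSums(incidence(coded4))), 1)
  unlink(f)
})

test_that("set bits per object never exceed the scale count, with equality when complete", {
  for (seed in 1:5) {
    fx <- randomTinySample(seed)
    nScales <- length(fx$scales@scales)
    expect_true(all(Matrix::rowSums(incidence(fx$sample)) == nScales))
  }
  # re-coding the training table against its own scales never clamps
  gen <- generateBioassay(nObjects = 80, nNumericScales = 4, nTextScales = 6,
                          activeRate = 0.3, nInformative = 2, effectSize = 1,
                          seed = 3)
  sc <- buildScales(gen$table)
  expect_no_warning(codeObjects(gen$table, sc))
})

test_that("scale sets survive a JSON round trip and coded samples export as triplets", {
  fx <- ingest(data.frame(id = paste0("o", 1:4), Outcome = c("A", "A", "B", "B"),
                          X = c("1.5", "2.5", "3.5", "4.5"),
                          T1 = c("u", "v", "u", "v")))
  f <- tempfile(fileext = ".json")
  writeScaleSet(fx$scales, f)
  sc2 <- readScaleSet(f)
  expect_identical(sc2@classScale, fx$scales@classScale)
  expect_equal(sc2@scales, fx$scales@scales)
  expect_identical(gradationInfo(sc2), gradationInfo(fx$scales))

  g <- tempfile(fileext = ".tsv")
  writeCodedTriplets(fx$sample, g)
  tri <- utils::read.table(g, sep = "\t", header = TRUE)
  expect_equal(nrow(tri), sum(incidence(fx$sample)))
  expect_true(all(tri$value == 1))
  unlink(c(f, g))
})
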