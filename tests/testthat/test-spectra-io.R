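test_that("readSpectra reads back what writeSpectra wrote, with meta columns", {
  ds <- SpectraSet(matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 4),
                   c("gel", "solution"),
                   meta = data.frame(meta_exp = c("e1", "e2")))
  p <- withr::local_tempfile(fileext = ".csv")
  writeSpectra(ds, p)
  rd <- readSpectra(p)
  expect_equal(nSpectra(rd), 2L)
  expect_equal(spectrumLength(rd), 4L)
  expect_equal(classLevels(rd), c("gel", "solution"))
  expect_identical(spectraValues(rd), spectraValues(ds))
  expect_equal(SummarizedExperiment::colData(rd)$meta_exp, c("e1", "e2"))
})

test_that("degenerate spectra files raise informative errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,label,v1,v2", p)
  expect_error(readSpectra(p), "no spectra")
  writeLines(c("id,label,v1,v2", "s1,gel,1,oops"), p)
  expect_error(readSpectra(p), "row")
  expect_error(readSpectra(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("write/read round-trips preserve values to full precision and are
           byte-stable", {
  for (seed in 1:20) {
    ds <- randomSpectraSet(n = 7, L = 5, seed = seed)
    p1 <- withr::local_tempfile(fileext = ".csv")
    p2 <- withr::local_tempfile(fileext = ".csv")
    writeSpectra(ds, p1)
    rd <- readSpectra(p1)
    expect_identical(spectraValues(rd), spectraValues(ds))
    writeSpectra(rd, p2)
    expect_identical(readLines(p1), readLines(p2))
  }
})

test_that("toSequenceIndex keeps values and records the frequency range", {
  v <- c(4, 2, 7)
  out <- toSequenceIndex(v, seq(26013.75, 37000, length.out = 3))
  expect_equal(as.numeric(out), v)
  expect_equal(attr(out, "freqRange"), c(26013.75, 37000))
  expect_equal(attr(out, "index"), 1:3)
  # two ranges, same length: identical index axes afterwards
  out2 <- toSequenceIndex(v, seq(27016.25, 40000, length.out = 3))
  expect_identical(attr(out, "index"), attr(out2, "index"))
  expect_equal(as.numeric(toSequenceIndex(5, 100)), 5)
  expect_error(toSequenceIndex(v, c(3, 2, 1)), "increasing")
  expect_error(toSequenceIndex(v, c(1, 2)), "equal length")
})

test_that("normalizeMinmax maps the global range affinely and inverts exactly", {
  ds <- SpectraSet(matrix(c(0, 5, 10, 2), 2), c("a", "b"))
  nd <- normalizeMinmax(ds, -1, 1)
  expect_equal(as.numeric(spectraValues(nd)), c(-1, 0, 1, -0.6))
  # already spanning [-1, 1]: unchanged
  ds2 <- SpectraSet(matrix(c(-1, 0.5, 1, 0), 2), c("a", "b"))
  expect_equal(spectraValues(normalizeMinmax(ds2)), spectraValues(ds2))
  # random data: denormalize(normalize(x)) == x
  rs <- randomSpectraSet(n = 12, L = 9, seed = 4)
  back <- denormalize(normalizeMinmax(rs))
  expect_lt(max(abs(spectraValues(back) - spectraValues(rs))), 1e-10)
  # every normalized element lies in [lo, hi]
  nv <- spectraValues(normalizeMinmax(rs, -1, 1))
  expect_true(all(nv >= -1 & nv <= 1))
  expect_warning(normalizeMinmax(SpectraSet(matrix(3, 2, 2), c("a", "b"))),
                 "constant")
})

test_that("resampleLength interpolates linearly and preserves endpoints", {
  expect_equal(resampleLength(c(0, 1, 2, 3), 2L), c(0, 3))
  x <- rnorm(800)
  expect_equal(resampleLength(x, 800L), x)
  # smooth spectrum down/up-sampling stays within the piecewise-linear
  # oracle's worst-case interpolation error bound (h^2/8 * max |f''|)
  t <- seq(0, 1, length.out = 800)
  smooth <- sin(2 * pi * t) + 0.5 * cos(6 * pi * t)
  down <- resampleLength(smooth, 200L)
  up <- resampleLength(down, 800L)
  h <- 799 / 199   # coarse grid spacing in fine-index units
  maxf2 <- max(abs(-(2 * pi / 799)^2 * sin(2 * pi * t) -
                     0.5 * (6 * pi / 799)^2 * cos(6 * pi * t)))
  expect_lt(max(abs(up - smooth)), 2 * h^2 / 8 * maxf2 + 1e-12)
  expect_error(resampleLength(x, 1L), "targetLength")
  ss <- randomSpectraSet(n = 3, L = 10, seed = 2)
  expect_equal(spectrumLength(resampleLength(ss, 4L)), 4L)
})

test_that("imbalanced splits realize the published designs exactly", {
  ds <- simulateDataset(SimConfig(length = 32L,
                                  nPerClass = c(solution = 181L, gel = 107L)))
  # Pluronic-style designs: majority 150 vs minority 2/4/6
  for (m in c(2L, 4L, 6L)) {
    sp <- makeImbalancedSplit(ds, ImbalanceSpec("solution", "gel", 150L, m), 1L)
    expect_equal(classCounts(sp$train)[["solution"]], 150L)
    expect_equal(classCounts(sp$train)[["gel"]], m)
    expect_equal(balancedRatio(sp$realized), m / 150)
  }
  expect_equal(round(balancedRatio(ImbalanceSpec("s", "g", 150, 4)), 3), 0.027)
  expect_equal(round(balancedRatio(ImbalanceSpec("g", "s", 120, 10)), 3), 0.083)
  # balanced case
  sp <- makeImbalancedSplit(ds, ImbalanceSpec("solution", "gel", 5L, 5L), 7L)
  expect_equal(balancedRatio(sp$realized), 1)
  expect_equal(nSpectra(sp$train), 10L)
  expect_error(
    makeImbalancedSplit(ds, ImbalanceSpec("solution", "gel", 150L, 120L), 1L),
    "gel")
})

test_that("splits are disjoint, exhaustive and seed-deterministic", {
  ds <- simulateDataset(SimConfig(length = 16L,
                                  nPerClass = c(solution = 30L, gel = 20L)))
  spec <- ImbalanceSpec("solution", "gel", 20L, 3L)
  for (seed in 1:50) {
    sp <- makeImbalancedSplit(ds, spec, seed)
    expect_equal(nSpectra(sp$train) + nSpectra(sp$test), nSpectra(ds))
    ids <- c(SummarizedExperiment::colData(sp$train)$id,
             SummarizedExperiment::colData(sp$test)$id)
    expect_equal(sort(ids), sort(SummarizedExperiment::colData(ds)$id))
  }
  a <- makeImbalancedSplit(ds, spec, 42L)
  b <- makeImbalancedSplit(ds, spec, 42L)
  expect_identical(SummarizedExperiment::colData(a$train)$id,
                   SummarizedExperiment::colData(b$train)$id)
  expect_false(identical(
    SummarizedExperiment::colData(makeImbalancedSplit(ds, spec, 43L)$train)$id,
    SummarizedExperiment::colData(a$train)$id))
})

test_that("SpectraSet and ImbalanceSpec validity catch broken objects", {
  expect_error(SpectraSet(matrix(c(1, NA), 1), c("a", "b")), "finite")
  expect_error(SpectraSet(matrix(1:4, 2), c("a", "b", "c")), "label")
  expect_error(ImbalanceSpec("a", "b", 3, 5), "exceed")
  expect_error(ImbalanceSpec("a", "a", 5, 3), "differ")
})
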