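test_that("gb_map is the signed G-B difference on dental pixels", {
  img <- mk_image(matrix(10L, 2, 2),
                  matrix(c(200L, 50L, 0L, 130L), 2, 2),
                  matrix(c(50L, 200L, 130L, 130L), 2, 2))
  m <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  gb <- gb_map(img, m)
  expect_equal(gb[1, 1], 150)
  expect_equal(gb[2, 1], -150)
  expect_true(is.na(gb[2, 2]))

  set.seed(3)
  img <- rand_image(30, 30)
  m <- matrix(runif(900) < 0.5, 30, 30)
  gb <- gb_map(img, m)
  for (i in 1:30) for (j in 1:30) {
    if (m[i, j])
      expect_identical(gb[i, j], img$pixels[i, j, 2] - img$pixels[i, j, 3])
    else expect_true(is.na(gb[i, j]))
  }
})

test_that("auto_delta is minus the absolute mean blue/green difference", {
  img <- uniform_image(10, 10, 0, 100, 160)
  m <- matrix(TRUE, 10, 10)
  expect_equal(auto_delta(img, m), -60)
  expect_equal(auto_delta(uniform_image(10, 10, 0, 120, 120), m), 0)

  set.seed(5)
  img <- rand_image(25, 25)
  m <- matrix(runif(625) < 0.6, 25, 25)
  g <- img$pixels[, , 2][m]; b <- img$pixels[, , 3][m]
  expect_equal(auto_delta(img, m), -abs(sum(b) / sum(m) - sum(g) / sum(m)))
  expect_lte(auto_delta(img, m), 0)
})

test_that("classification follows the threshold inequalities at the boundaries", {
  delta <- -30; l <- -90
  gbv <- c(1L, 0L, -30L, -31L, -90L, -91L)
  img <- mk_image(matrix(10L, 1, 6),
                  matrix(200L + gbv, 1, 6),
                  matrix(200L, 1, 6))
  gb <- gb_map(img, matrix(TRUE, 1, 6))
  lab <- classify_plaque(gb, img, delta, l)
  codes <- plaque_classes()
  expect_equal(as.vector(lab$labels),
               unname(codes[c("VISIBLE", "NV1", "NV1", "NV2", "NV2", "NONPLAQUE")]))
})

test_that("collapsed thresholds delta = l = 0 leave only VISIBLE/NV1/NONPLAQUE", {
  set.seed(9)
  img <- rand_image(40, 40)
  m <- matrix(TRUE, 40, 40)
  lab <- classify_plaque(gb_map(img, m), img, 0, 0)
  cc <- class_counts(lab)
  expect_equal(cc[["NV2"]], 0L)
  # NV1 can only hold pixels at exactly G-B = 0
  expect_equal(cc[["NV1"]], sum(img$pixels[, , 2] == img$pixels[, , 3] &
                                img$pixels[, , 2] > 0L))
})

test_that("pixels with a zero green or blue channel never enter the risk classes", {
  img <- mk_image(matrix(10L, 1, 3),
                  matrix(c(0L, 50L, 0L), 1, 3),
                  matrix(c(50L, 0L, 0L), 1, 3))
  m <- matrix(TRUE, 1, 3)
  lab <- classify_plaque(gb_map(img, m), img, -100, -200)
  codes <- plaque_classes()
  # G=0 (G-B<0): guard applies; B=0 with G>0 is VISIBLE via G-B>0; both 0: guard
  expect_equal(as.vector(lab$labels),
               unname(codes[c("NONPLAQUE", "VISIBLE", "NONPLAQUE")]))
})

test_that("vectorized classification equals the per-pixel loop on random images", {
  set.seed(17)
  for (i in 1:5) {
    img <- rand_image(48, 48)
    m <- matrix(runif(48 * 48) < 0.7, 48, 48)
    delta <- -sample(0:80, 1)
    l <- delta - sample(0:120, 1)
    lab <- classify_plaque(gb_map(img, m), img, delta, l)
    expect_identical(lab$labels, oracle_classify(img, m, delta, l))
  }
})

test_that("classification rejects l > delta and is idempotent", {
  img <- rand_image(10, 10)
  gb <- gb_map(img, matrix(TRUE, 10, 10))
  expect_error(classify_plaque(gb, img, -50, -10),
               class = "plaquant_parameter_error")
  a <- classify_plaque(gb, img, -20, -60)
  b <- classify_plaque(gb, img, -20, -60)
  expect_identical(a, b)
})

test_that("every dental pixel gets exactly one non-OUTSIDE label", {
  set.seed(31)
  img <- rand_image(100, 100)
  m <- matrix(runif(1e4) < 0.6, 100, 100)
  lab <- classify_plaque(gb_map(img, m), img, -40, -90)
  codes <- plaque_classes()
  expect_true(all(lab$labels[m] != codes[["OUTSIDE"]]))
  expect_true(all(lab$labels[!m] == codes[["OUTSIDE"]]))
  cc <- class_counts(lab)
  expect_equal(sum(cc[c("VISIBLE", "NV1", "NV2", "NONPLAQUE")]), sum(m))
})

test_that("making delta more negative grows NV1 at the expense of NV2 only", {
  set.seed(19)
  img <- rand_image(64, 64)
  m <- matrix(TRUE, 64, 64)
  gb <- gb_map(img, m)
  l <- -200
  prev <- NULL
  for (delta in seq(0, -150, by = -10)) {
    cc <- class_counts(classify_plaque(gb, img, delta, l))
    if (!is.null(prev)) {
      expect_gte(cc[["NV1"]], prev[["NV1"]])
      expect_lte(cc[["NV2"]], prev[["NV2"]])
      expect_equal(cc[["VISIBLE"]], prev[["VISIBLE"]])
      expect_equal(cc[["NONPLAQUE"]], prev[["NONPLAQUE"]])
    }
    prev <- cc
  }
})

test_that("gb_histogram counts every dental pixel once per integer bin", {
  img <- uniform_image(10, 10, 0, 60, 100)
  m <- matrix(TRUE, 10, 10)
  h <- gb_histogram(gb_map(img, m))
  expect_equal(sum(h), 100)
  expect_equal(unname(h[["-40"]]), 100)

  empty <- gb_histogram(gb_map(img, matrix(FALSE, 10, 10)))
  expect_equal(sum(empty), 0)

  set.seed(29)
  img <- rand_image(35, 35)
  m <- matrix(runif(35 * 35) < 0.5, 35, 35)
  gb <- gb_map(img, m)
  expect_equal(as.integer(gb_histogram(gb)), unname(oracle_histogram(gb)))
  expect_equal(sum(gb_histogram(gb)), sum(m))
})

test_that("auto_l finds the first crossing scanning up from -255", {
  mk_hist <- function(counts_at = integer(0)) {
    h <- setNames(integer(511), -255:255)
    for (nm in names(counts_at)) h[[nm]] <- counts_at[[nm]]
    structure(h, class = "gb_histogram")
  }
  # identical histograms: fallback to delta, NV2 empty
  h <- mk_hist(c("-40" = 10))
  l <- auto_l(h, h, delta = -25)
  expect_equal(as.numeric(l), -25)
  expect_true(attr(l, "fallback"))

  # single crossing bin at -80
  cur <- mk_hist(c("-80" = 5)); ref <- mk_hist()
  expect_equal(as.numeric(auto_l(cur, ref, -10)), -80)

  set.seed(37)
  for (i in 1:20) {
    cur <- mk_hist(); ref <- mk_hist()
    cur[1:256] <- rpois(256, 2); ref[1:256] <- rpois(256, 2)
    delta <- -sample(0:50, 1)
    expect_equal(as.numeric(auto_l(cur, ref, delta)),
                 oracle_auto_l(cur, ref, delta))
  }
})

test_that("visible histogram mass is non-decreasing as synthetic plaque grows", {
  ts <- as.POSIXct("2020-03-02 09:00:00", tz = "UTC") + c(0, 24, 48, 72, 96) * 3600
  series <- render_series(scene_spec(seed = 21), rate = 0.75, timestamps = ts)
  params <- processing_params()
  mass <- vapply(series, function(s) {
    dm <- segment_dental_area(s$moment$images[[1]], params)
    h <- gb_histogram(gb_map(s$moment$images[[1]], dm))
    sum(h[257:511]) / sum(h)
  }, numeric(1))
  expect_true(all(diff(mass) > -1e-12))
})
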