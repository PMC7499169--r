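# build a region_labels + gb_map pair directly from a label matrix and
# per-pixel G-B values
mk_labels <- function(lab, gbv = NULL, delta = -30, l = -60) {
  codes <- plaque_classes()
  labels <- structure(list(labels = lab, delta_used = delta, l_used = l),
                      class = "region_labels")
  gb <- matrix(NA_integer_, nrow(lab), ncol(lab))
  dental <- lab != codes[["OUTSIDE"]]
  if (is.null(gbv)) gbv <- 0L
  gb[dental] <- gbv
  gb[lab == codes[["NONPLAQUE"]] ] <- -100L
  list(labels = labels, gb = structure(gb, class = "gb_map"))
}

test_that("area percentages are exact ratios summing to 100", {
  codes <- plaque_classes()
  lab <- matrix(codes[["NONPLAQUE"]], 40, 25)
  lab[1:10, ] <- codes[["VISIBLE"]]         # 250 of 1000
  x <- mk_labels(lab)
  expect_equal(area_percent(x$labels, "VISIBLE"), 25)
  total <- sum(vapply(c("VISIBLE", "NV1", "NV2", "NONPLAQUE"),
                      function(cl) area_percent(x$labels, cl), numeric(1)))
  expect_equal(total, 100, tolerance = 1e-12)

  set.seed(4)
  lab <- matrix(sample(unname(codes), 600, TRUE), 20, 30)
  if (!any(lab != codes[["OUTSIDE"]])) lab[1, 1] <- codes[["VISIBLE"]]
  x <- mk_labels(lab)
  for (cl in c("VISIBLE", "NV1", "NV2", "NONPLAQUE")) {
    expect_equal(area_percent(x$labels, cl),
                 100 * sum(lab == codes[[cl]]) / sum(lab != codes[["OUTSIDE"]]))
  }
})

test_that("API index hits its closed-form values and limits", {
  codes <- plaque_classes()
  # no visible plaque -> 0
  lab <- matrix(codes[["NONPLAQUE"]], 10, 10)
  x <- mk_labels(lab)
  expect_equal(api_index(x$labels, x$gb), 0)

  # full dental area visible at saturated G-B -> 100
  lab <- matrix(codes[["VISIBLE"]], 10, 10)
  x <- mk_labels(lab, gbv = 255L)
  expect_equal(api_index(x$labels, x$gb), 100)

  # half the area visible at uniform G-B = 102 -> 0.5 * 102/255 * 100 = 20
  lab <- matrix(codes[["NONPLAQUE"]], 10, 10)
  lab[1:5, ] <- codes[["VISIBLE"]]
  gb <- matrix(NA_integer_, 10, 10)
  gb[1:5, ] <- 102L; gb[6:10, ] <- -100L
  labels <- structure(list(labels = lab, delta_used = -30, l_used = -60),
                      class = "region_labels")
  expect_equal(api_index(labels, structure(gb, class = "gb_map")), 20)
})

test_that("API is bounded and monotone in area and intensity", {
  codes <- plaque_classes()
  base <- matrix(codes[["NONPLAQUE"]], 20, 20)
  vals <- numeric(0)
  for (frac in c(0.1, 0.3, 0.6, 0.9)) {
    lab <- base
    lab[seq_len(round(frac * 400))] <- codes[["VISIBLE"]]
    for (int in c(20L, 90L, 200L)) {
      x <- mk_labels(lab, gbv = int)
      x$gb[lab == codes[["VISIBLE"]]] <- int
      a <- api_index(x$labels, x$gb)
      expect_gte(a, 0); expect_lte(a, 100)
      vals <- c(vals, a)
    }
  }
  m <- matrix(vals, nrow = 3)            # rows: intensity, cols: area fraction
  expect_true(all(diff(t(m)[, 1]) > 0))  # monotone in area at fixed intensity
  expect_true(all(apply(m, 2, diff) > 0))# monotone in intensity at fixed area
})

test_that("growth index is the area difference per elapsed hour", {
  expect_equal(area_growth_index(72, 0, 96), 0.75)
  expect_equal(area_growth_index(40, 40, 10), 0)
  expect_lt(area_growth_index(10, 30, 10), 0)
  expect_error(area_growth_index(50, 0, 0),
               class = "plaquant_reference_moment_error")
})

test_that("area time extrapolates linearly to 100% coverage", {
  expect_equal(area_time_index(70, 0.75), 30 / 0.75 / 24)
  expect_equal(round(area_time_index(70, 0.75), 2), 1.67)
  expect_equal(area_time_index(100, 0.5), 0)
  expect_equal(area_time_index(120, 0.5), 0)
  expect_true(is.na(area_time_index(50, 0)))
  expect_true(is.na(area_time_index(50, -1)))
})

test_that("growth and area-time indices are algebraically consistent", {
  set.seed(8)
  for (i in 1:50) {
    a <- runif(1, 0, 99.9); t <- runif(1, 1, 200)
    rate <- area_growth_index(a, 0, t)
    if (rate <= 0) next
    days <- area_time_index(a, rate)
    expect_equal(days * 24 * rate + a, 100, tolerance = 1e-9)
  }
})

test_that("normalization factor is the reference/current pixel-count ratio", {
  m1 <- matrix(TRUE, 100, 100)                     # 10000 px
  expect_equal(normalization_factor(m1, m1), 1)
  m2 <- matrix(FALSE, 100, 100); m2[1:80, ] <- TRUE # 8000 px
  expect_equal(normalization_factor(m2, m1), 1.25)
  expect_error(normalization_factor(matrix(FALSE, 5, 5), m1),
               class = "plaquant_empty_dental_area")

  set.seed(12)
  for (i in 1:20) {
    nc <- sample(1:5000, 1); nr <- sample(1:5000, 1)
    cur <- matrix(FALSE, 80, 80); cur[seq_len(nc)] <- TRUE
    ref <- matrix(FALSE, 80, 80); ref[seq_len(nr)] <- TRUE
    expect_equal(normalization_factor(cur, ref) * nc, nr)  # exact
  }
})

test_that("measure_moment fills absolute and relative fields coherently", {
  codes <- plaque_classes()
  lab_ref <- matrix(codes[["NONPLAQUE"]], 30, 30)
  lab_ref[1, 1:3] <- codes[["VISIBLE"]]
  ref <- mk_labels(lab_ref, gbv = 50L)

  lab_now <- matrix(codes[["NONPLAQUE"]], 30, 30)
  lab_now[1:15, ] <- codes[["VISIBLE"]]
  lab_now[16:20, ] <- codes[["NV1"]]
  now <- mk_labels(lab_now, gbv = 80L)

  # self-comparison: no growth
  self <- measure_moment(ref$labels, ref$gb, ref$labels, ref$gb,
                         elapsed_hours = 24)
  expect_equal(self$growth_index_visible, 0)
  expect_true(is.na(self$area_time_visible))

  m <- measure_moment(now$labels, now$gb, ref$labels, ref$gb,
                      elapsed_hours = 48)
  expect_equal(m$visible_percent, 50)
  expect_equal(m$growth_index_visible, (50 - 100 * 3 / 900) / 48)
  expect_equal(m$normalization_factor, 1)
  # total plaque covers more area and grows faster -> reaches 100% sooner
  expect_lte(m$area_time_total, m$area_time_visible)

  # reference rows carry NA relative fields
  refrow <- measure_moment(ref$labels, ref$gb)
  expect_true(is.na(refrow$growth_index_visible))
  expect_true(is.na(refrow$normalization_factor))
  expect_equal(refrow$visible_percent + refrow$nv1_percent +
                 refrow$nv2_percent + refrow$nonplaque_percent, 100,
               tolerance = 1e-9)
})

test_that("indices ignore pixel positions (translation and flip invariance)", {
  sc <- render_scene(scene_spec(seed = 15))
  p <- processing_params()
  base <- process_image(sc$image, p)
  m0 <- measure_moment(base$labels, base$gb)

  flip <- sc$image
  flip$pixels <- flip$pixels[nrow(flip$pixels):1, , , drop = FALSE]
  fr <- process_image(flip, p)
  m1 <- measure_moment(fr$labels, fr$gb)

  shift <- sc$image
  # rotate through background-only columns so no tooth is split at the edge
  shift$pixels <- shift$pixels[, c(341:ncol(shift$pixels), 1:340), , drop = FALSE]
  sr <- process_image(shift, p)
  m2 <- measure_moment(sr$labels, sr$gb)

  for (col in c("dental_pixels", "visible_percent", "api_index",
                "mean_visible_intensity", "delta_used")) {
    expect_equal(m1[[col]], m0[[col]])
    expect_equal(m2[[col]], m0[[col]])
  }
})
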