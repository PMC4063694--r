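# Stage-2: thresholding, component labeling, morphometry, classification
# and the assembled detector.

test_that("thresholding retains only pixels above mean + k*sd", {
  expect_equal(threshold_response(matrix(0, 8, 8) + 0), matrix(0, 8, 8))

  # 8x8 fixture with hand-listed values: threshold computed directly
  withr::with_seed(101, {
    vals <- round(runif(64, 0, 10), 1)
  })
  img <- matrix(vals, 8, 8)
  m <- sum(vals) / 64
  d <- sqrt(sum((vals - m)^2) / 63)
  out <- threshold_response(img, 1.8)
  expect_identical(out != 0, img > m + 1.8 * d)
  expect_identical(out[out != 0], img[img > m + 1.8 * d])

  # a pixel at m + 2d survives, one at m + 1.5d does not: fixed-point
  # construction so the probes sit at exact multiples of the final SD
  base <- rep(c(-1, 1), 50)
  probes <- c(0, 0)
  for (i in 1:60) {
    v <- c(base, probes)
    probes <- mean(v) + c(2, 1.5) * sd(v)
  }
  out2 <- threshold_response(matrix(c(base, probes), 2), 1.8)
  v <- c(base, probes)
  expect_true(probes[1] %in% out2)       # m + 2d retained
  expect_false(probes[2] %in% out2[out2 != 0])  # m + 1.5d zeroed
})

test_that("component labeling follows the connectivity rule and matches flood fill", {
  m <- matrix(0, 3, 3)
  m[1, 1] <- 1
  m[2, 2] <- 1
  expect_identical(attr(label_components(m, 8), "n_components"), 1L)
  expect_identical(attr(label_components(m, 4), "n_components"), 2L)

  withr::with_seed(111, {
    for (rep in 1:5) {
      binary <- matrix(rbinom(400, 1, 0.35), 20, 20)
      for (conn in c(4, 8)) {
        lab <- label_components(binary, conn)
        oracle <- oracle_flood_fill(binary, conn)
        expect_identical(attr(lab, "n_components"), oracle$n_components)
        # identical partition: labels agree up to renaming
        expect_identical(unname(lab != 0), unname(oracle$labels != 0))
        pairs <- unique(cbind(lab[lab != 0], oracle$labels[lab != 0]))
        expect_identical(nrow(pairs), oracle$n_components)
      }
    }
  })
})

test_that("4-connectivity labeling agrees with EBImage bwlabel", {
  withr::with_seed(112, {
    binary <- matrix(rbinom(900, 1, 0.4), 30, 30)
  })
  lab <- label_components(binary, 4)
  ref <- EBImage::bwlabel(binary)
  expect_identical(attr(lab, "n_components"), as.integer(max(ref)))
})

test_that("blob morphometry matches closed-form moment values", {
  # single pixel
  m <- matrix(0, 5, 5)
  m[3, 3] <- 1
  f <- blob_features(label_components(m))
  expect_equal(f$l_maj, 4 * sqrt(1 / 12), tolerance = 1e-12)
  expect_equal(f$l_min, 4 * sqrt(1 / 12), tolerance = 1e-12)
  expect_equal(f$aspect, 1, tolerance = 1e-12)
  expect_equal(f$area, 1)
  expect_equal(c(f$centroid_row, f$centroid_col), c(3, 3))

  # horizontal 1x4 line: coordinate variance 1.25, plus 1/12 per axis
  m <- matrix(0, 5, 8)
  m[3, 2:5] <- 1
  f <- blob_features(label_components(m))
  expect_equal(f$area, 4)
  expect_equal(f$l_maj, 4 * sqrt(1.25 + 1 / 12), tolerance = 1e-12)
  expect_equal(f$l_min, 4 * sqrt(1 / 12), tolerance = 1e-12)
  expect_equal(f$aspect, 4, tolerance = 1e-12)

  # 2x12 filled rectangle: per-axis variance (n^2-1)/12 + 1/12 = n^2/12
  m <- matrix(0, 6, 16)
  m[3:4, 3:14] <- 1
  f <- blob_features(label_components(m))
  expect_equal(f$area, 24)
  expect_equal(f$aspect, 6, tolerance = 1e-12)
  expect_equal(f$l_maj, 4 * sqrt(144 / 12), tolerance = 1e-12)

  # centroid lies inside the bounding box of every random blob
  withr::with_seed(121, {
    binary <- matrix(rbinom(400, 1, 0.3), 20, 20)
  })
  lab <- label_components(binary)
  feats <- blob_features(lab)
  for (i in seq_len(nrow(feats))) {
    px <- which(lab == feats$label_id[i], arr.ind = TRUE)
    expect_gte(feats$centroid_row[i], min(px[, 1]))
    expect_lte(feats$centroid_row[i], max(px[, 1]))
    expect_gte(feats$centroid_col[i], min(px[, 2]))
    expect_lte(feats$centroid_col[i], max(px[, 2]))
    expect_gte(feats$aspect[i], 1)
  }
})

test_that("classification applies the strict area-then-aspect rule", {
  f <- tibble::tibble(area = c(8, 9, 50, 50, 4),
                      aspect = c(1, 1, 3.5, 3, 4))
  expect_identical(as.character(classify_blobs(f)$class),
                   c("noise", "cell", "vessel", "cell", "noise"))

  # exhaustive grid against the literal rule evaluator
  grid <- expand.grid(area = 1:20, aspect = seq(1, 8, by = 0.25))
  got <- as.character(classify_blobs(grid)$class)
  want <- mapply(oracle_classify, grid$area, grid$aspect)
  expect_identical(got, unname(want))

  # aspect derived from axis lengths when absent
  f2 <- tibble::tibble(area = 50, l_maj = 10, l_min = 2)
  expect_identical(as.character(classify_blobs(f2)$class), "vessel")
})

test_that("thresholding is monotone in k and classification in a_min", {
  withr::with_seed(131, {
    resp <- matrix(rnorm(2500), 50, 50)
  })
  n_fg <- vapply(seq(0.5, 3, by = 0.25),
                 function(k) sum(threshold_response(resp, k) != 0), 0)
  expect_true(all(diff(n_fg) <= 0))

  feats <- blob_features(label_components(threshold_response(resp, 1)))
  n_keep <- vapply(seq(1, 30, by = 1), function(a_min) {
    cls <- classify_blobs(feats, detection_params(a_min = a_min))$class
    sum(cls != "noise")
  }, 0)
  expect_true(all(diff(n_keep) <= 0))
})

test_that("the detector counts synthetic scenes and conserves blob totals", {
  expect_error(detect_cells(matrix(1, 10, 10)), "16 x 16")

  blank <- detect_cells(matrix(0.5, 64, 64))
  expect_identical(blank$n_blobs, 0L)
  expect_identical(blank$n_cells, 0L)

  sim <- generate_image(synthetic_spec(height = 280, width = 280,
                                       n_cells = 25, seed = 7))
  det <- detect_cells(sim$image)
  expect_identical(det$n_cells, 25L)
  expect_identical(det$n_cells + det$n_vessels + det$n_noise, det$n_blobs)
  expect_identical(det$n_blobs,
                   attr(label_components(threshold_response(
                     preprocess_image(sim$image))), "n_components"))

  # every reported centroid within 2 px of a true centre
  cells <- dplyr::filter(det$blobs, class == "cell")
  d2 <- outer(cells$centroid_row, sim$truth$cell_centers$row, "-")^2 +
    outer(cells$centroid_col, sim$truth$cell_centers$col, "-")^2
  expect_lt(max(sqrt(apply(d2, 1, min))), 2)

  # adding one long bright ridge leaves the cell count intact and
  # introduces at least one vessel
  simv <- generate_image(synthetic_spec(height = 280, width = 280,
                                        n_cells = 25, n_vessels = 1,
                                        cell_amplitude_range = c(0.25, 0.4),
                                        seed = 2))
  detv <- detect_cells(simv$image)
  expect_identical(detv$n_cells, 25L)
  expect_gte(detv$n_vessels, 1L)
})

test_that("detection is deterministic and its tidiers are consistent", {
  sim <- generate_image(synthetic_spec(height = 200, width = 200,
                                       n_cells = 12, seed = 5))
  d1 <- detect_cells(sim$image)
  d2 <- detect_cells(sim$image)
  expect_identical(d1$blobs, d2$blobs)
  expect_identical(d1$labels, d2$labels)

  expect_identical(tidy(d1), d1$blobs)
  g <- glance(d1)
  expect_identical(g$n_cells, d1$n_cells)
  expect_identical(g$n_blobs, g$n_cells + g$n_vessels + g$n_noise)
  p <- autoplot(d1)
  expect_s3_class(p, "ggplot")
})
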