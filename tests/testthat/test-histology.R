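# Pixel-based histology quantification.

test_that("pure-palette images classify to the exact configured fractions", {
  h <- simulate_histology(seed = 1, width = 200, height = 200,
                          frac_blue = 0.3, frac_red = 0.6)
  cls <- classify_colors(h$image)
  fi <- fibrotic_index(cls)
  expect_equal(fi$pct_blue, 30)
  expect_equal(fi$pct_red, 60)
  expect_equal(fi$index, 0.5)
  z <- simulate_histology(seed = 2, width = 100, height = 100,
                          frac_blue = 0, frac_red = 0.7)
  expect_equal(fibrotic_index(classify_colors(z$image))$index, 0)
})

test_that("grayscale images are all background; no red flags undefined", {
  g <- array(0.5, dim = c(40, 40, 3))
  expect_warning(cls <- classify_colors(rgb_image(g)), "background")
  expect_equal(unname(cls$counts[["background"]]), 1600)
  fi <- fibrotic_index(cls)
  expect_true(fi$undefined)
  expect_true(is.na(fi$index))
})

test_that("label fractions equal a brute-force pixel count oracle", {
  h <- simulate_histology(seed = 5, width = 120, height = 80,
                          frac_blue = 0.22, frac_red = 0.55)
  cls <- classify_colors(h$image)
  lab <- cls$labels
  brute <- c(blue = 0L, red = 0L)
  for (i in seq_len(nrow(lab))) for (j in seq_len(ncol(lab))) {
    if (lab[i, j] == "blue") brute[["blue"]] <- brute[["blue"]] + 1L
    if (lab[i, j] == "red") brute[["red"]] <- brute[["red"]] + 1L
  }
  fi <- fibrotic_index(cls)
  expect_equal(fi$pct_blue, 100 * brute[["blue"]] / length(lab))
  expect_equal(fi$index, brute[["blue"]] / brute[["red"]])
})

test_that("hue perturbation within 10 degrees barely moves the fractions", {
  h <- simulate_histology(seed = 8, width = 150, height = 150,
                          frac_blue = 0.3, frac_red = 0.6)
  img <- h$image$img
  set.seed(split_seed(8, "hue-jitter"))
  hsv <- grDevices::rgb2hsv(rbind(as.vector(img[, , 1]),
                                  as.vector(img[, , 2]),
                                  as.vector(img[, , 3])), maxColorValue = 1)
  hj <- (hsv[1, ] * 360 + runif(ncol(hsv), -10, 10)) %% 360
  pert <- grDevices::hsv(hj / 360, hsv[2, ], hsv[3, ])
  rgbp <- grDevices::col2rgb(pert) / 255
  img2 <- array(0, dim = dim(img))
  for (ch in 1:3) img2[, , ch] <- matrix(rgbp[ch, ], dim(img)[1], dim(img)[2])
  fi2 <- fibrotic_index(classify_colors(rgb_image(img2)))
  expect_lt(abs(fi2$pct_blue - 30), 2)
  expect_lt(abs(fi2$pct_red - 60), 2)
})

test_that("pixel fractions are invariant to rotation and mirroring", {
  h <- simulate_histology(seed = 3, width = 90, height = 60,
                          frac_blue = 0.25, frac_red = 0.5)
  base <- fibrotic_index(classify_colors(h$image))
  rot <- h$image
  rot$img <- aperm(h$image$img, c(2, 1, 3))[dim(h$image$img)[2]:1, , ]
  mir <- h$image
  mir$img <- h$image$img[, dim(h$image$img)[2]:1, ]
  expect_equal(fibrotic_index(classify_colors(rot))$index, base$index)
  expect_equal(fibrotic_index(classify_colors(mir))$index, base$index)
})

test_that("planted ellipse areas match the analytic value within 2%", {
  h <- simulate_histology(seed = 4, width = 400, height = 400,
                          cell_areas_um2 = rep(pi * 10 * 12.5, 9),
                          scale_um_per_px = 1)
  res <- cell_areas(h$image)
  expect_equal(res$n_cells, 9)
  expect_true(all(abs(res$areas_um2 - pi * 10 * 12.5) / (pi * 10 * 12.5) < 0.02))
  expect_false(res$meets_inclusion)  # 9 < 20 cells
  # areas scale as the square of the physical scale
  h2 <- simulate_histology(seed = 4, width = 400, height = 400,
                           cell_areas_um2 = rep(pi * 10 * 12.5, 9),
                           scale_um_per_px = 1)
  h2$image$scale_um_per_px <- 2
  res2 <- cell_areas(h2$image)
  expect_equal(sort(res2$areas_um2), sort(res$areas_um2) * 4)
})

test_that("two disjoint identical ellipses measure equal areas", {
  mask <- matrix(FALSE, 160, 300)
  ell <- function(cx, cy, ax, ay) {
    outer((seq_len(160) - cy)^2 / ay^2, (seq_len(300) - cx)^2 / ax^2, "+") <= 1
  }
  mask <- ell(75, 80, 12, 10) | ell(225, 80, 12, 10)
  res <- cell_areas(mask, scale_um_per_px = 1)
  expect_equal(res$n_cells, 2)
  expect_lt(abs(diff(res$areas_um2)), 1)
  empty <- matrix(FALSE, 50, 50)
  expect_warning(r0 <- cell_areas(empty, scale_um_per_px = 1), "no cells")
  expect_equal(r0$n_cells, 0)
})

test_that("positive-pixel fraction matches construction, 0 and 1 extremes", {
  tu <- simulate_tunel(seed = 2, frac_positive = 0.25)
  expect_equal(positive_pixel_fraction(tu$image)$fraction_positive, 0.25,
               tolerance = 0.01)
  none <- simulate_tunel(seed = 3, frac_positive = 0)
  expect_equal(positive_pixel_fraction(none$image)$fraction_positive, 0)
  all_pos <- simulate_tunel(seed = 4, frac_positive = 1)
  expect_equal(positive_pixel_fraction(all_pos$image)$fraction_positive, 1)
})

test_that("mean intensity equals the brute-force mean, masked or not", {
  set.seed(split_seed(12, "intensity"))
  img <- matrix(runif(500), 20, 25)
  expect_equal(mean_intensity(img), sum(img) / length(img), tolerance = 1e-12)
  half <- matrix(c(rep(0, 250), rep(100, 250)), 20, 25)
  expect_equal(mean_intensity(half), 50)
  mask <- img > 0.5
  expect_equal(mean_intensity(img, mask), sum(img[mask]) / sum(mask),
               tolerance = 1e-12)
  expect_error(mean_intensity(img, matrix(FALSE, 20, 25)), "empty mask")
})
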