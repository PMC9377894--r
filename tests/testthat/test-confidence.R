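test_that("image standard deviation is the population SD", {
  expect_equal(image_std(matrix(0.3, 5, 5)), 0)
  # fair Bernoulli {0,1}: SD = 0.5 in closed form
  expect_equal(image_std(matrix(c(0, 1), 4, 4)), 0.5)
  set.seed(5)
  for (i in 1:20) {
    img <- matrix(runif(63), 7, 9)
    m <- sum(img) / length(img)
    twopass <- sqrt(sum((img - m)^2) / length(img))
    expect_lt(abs(image_std(img) - twopass), 1e-12)
  }
})

test_that("quadrant means follow the floor(n/2) split rule", {
  img <- matrix(0.2, 4, 4)
  expect_equal(unname(quadrant_means(img)), rep(0.2, 4))
  blocks <- rbind(cbind(matrix(0.1, 2, 2), matrix(0.2, 2, 2)),
                  cbind(matrix(0.3, 2, 2), matrix(0.4, 2, 2)))
  expect_equal(unname(quadrant_means(blocks)), c(0.1, 0.2, 0.3, 0.4))
  set.seed(13)
  for (i in 1:20) {
    img <- matrix(runif(35), 5, 7)   # odd dims: extra row/col bottom/right
    expect_equal(unname(quadrant_means(img)), oracle_quadrant_means(img))
  }
  expect_error(quadrant_means(matrix(1, 1, 5)), "validation error")
})

test_that("confidence interval bounds are mean +/- 1.96 sigma", {
  b <- ci_bounds(0.5, 0.1)
  expect_equal(b$lower, 0.304)
  expect_equal(b$upper, 0.696)
  z0 <- ci_bounds(0.7, 0)
  expect_equal(z0$lower, 0.7)
  expect_equal(z0$upper, 0.7)
  set.seed(2)
  for (i in 1:20) {
    a <- runif(1); s <- runif(1, 0.01, 1)
    b <- ci_bounds(a, s)
    expect_lt(b$lower, a); expect_gt(b$upper, a)
  }
  expect_error(ci_bounds(0.5, -0.1), "parameter error")
})

test_that("pixel remap reproduces the frozen worked example", {
  w <- make_worked_example()
  expect_equal(unname(quadrant_means(w$slice)), unname(w$quadrant_means))
  expect_equal(image_std(w$slice), w$sigma)
  b <- confidence_bounds(w$slice)
  expect_equal(unname(b$lower), unname(w$lower))
  expect_equal(unname(b$upper), unname(w$upper))
  expect_equal(remap_pixels(w$slice, b), w$remapped)
})

test_that("remap branches follow the three-band rule", {
  # hand-built bounds: mean 0.5, sigma such that A1 = 0.3
  img <- matrix(c(0.9, 0.4, 0.1, 0.5), 2, 2)
  b <- structure(list(quadrant_means = rep(0.5, 4),
                      sigma = 0.2 / 1.96,
                      lower = rep(0.3, 4), upper = rep(0.7, 4), z = 1.96),
                 class = "confidence_bounds")
  r <- remap_pixels(img, b)
  expect_equal(r[1, 1], 0.9)   # above mean: kept
  expect_equal(r[2, 1], 0.9)   # middle band: 0.4 + 0.5
  expect_equal(r[1, 2], 0.5)   # below A1: assigned the mean
  expect_equal(r[2, 2], 0.5)   # at the mean: kept
})

test_that("remap never darkens and is idempotent above the mean", {
  set.seed(17)
  for (i in 1:20) {
    img <- matrix(runif(144), 12, 12)
    b <- confidence_bounds(img)
    r <- remap_pixels(img, b)
    expect_true(all(r >= 0 & r <= 1))
    # output >= min(input, quadrant mean) everywhere
    q <- crcd:::.quadrant_ranges(12L, 12L)
    for (k in 1:4) {
      p <- img[q[[k]]$rows, q[[k]]$cols]
      rr <- r[q[[k]]$rows, q[[k]]$cols]
      expect_true(all(rr >= pmin(p, b$quadrant_means[k]) - 1e-12))
      # pixels already >= their quadrant mean are untouched
      expect_equal(rr[p >= b$quadrant_means[k]], p[p >= b$quadrant_means[k]])
    }
  }
})

test_that("Haar smoothing averages 2x2 blocks and keeps shape", {
  expect_equal(dwt_smooth(matrix(0.4, 6, 6)), matrix(0.4, 6, 6))
  cb <- matrix(c(0, 1), 8, 8)  # checkerboard columns within 2x2 blocks
  expect_equal(dwt_smooth(cb), matrix(0.5, 8, 8))
  odd <- matrix(runif(35), 5, 7)
  expect_equal(dim(dwt_smooth(odd)), c(5L, 7L))
  # block means: compare one block by hand
  img <- matrix(runif(16), 4, 4)
  sm <- dwt_smooth(img)
  expect_equal(sm[1, 1], mean(img[1:2, 1:2]))
  expect_equal(sm[2, 2], mean(img[1:2, 1:2]))
  expect_equal(sm[3, 4], mean(img[3:4, 3:4]))
})

test_that("multi-level Otsu separates tight modes and reduces to binarize", {
  set.seed(31)
  v <- c(rnorm(300, 0.1, 0.01), rnorm(300, 0.5, 0.01), rnorm(300, 0.9, 0.01))
  img <- matrix(pmin(pmax(v, 0), 1), 30, 30)
  lab <- multi_threshold(img, 3)
  expect_equal(sort(unique(as.vector(lab))), 0:2)
  expect_true(all(lab[img < 0.3] == 0))
  expect_true(all(lab[img > 0.3 & img < 0.7] == 1))
  expect_true(all(lab[img > 0.7] == 2))
  # class index non-decreasing in intensity
  o <- order(as.vector(img))
  expect_true(all(diff(lab[o]) >= 0))
  # classes = 2 equals auto binarize
  bi <- matrix(rep(c(0.2, 0.8), 50), 10, 10)
  expect_identical(multi_threshold(bi, 2) == 1, binarize(bi, "auto"))
  expect_error(multi_threshold(matrix(c(0, 1), 4, 4), 3), "degenerate-input")
})

test_that("confidence region recovers a bright tumour within the blob", {
  for (seed in 1:5) {
    ph <- make_phantom(phantom_spec(seed = seed))
    fit <- crcd(ph, refine_contour = FALSE)
    expect_gte(dice(fit$mask, phantom_truth_union(ph)), 0.90)
    # mask confined to the dilated blob and to the top class
    rad <- (fit$params$rsf$kernel_size - 1) %/% 2
    dil <- crcd:::.dilate_disc(fit$resultant$mask, rad)
    expect_true(all(!fit$mask | dil))
    expect_true(all(fit$region$class_labels[fit$mask] ==
                      max(fit$region$class_labels)))
  }
})

test_that("an empty resultant blob yields an empty region mask", {
  img <- matrix(runif(64), 8, 8)
  cr <- confidence_region(img, matrix(FALSE, 8, 8))
  expect_true(!any(cr$mask))
})

test_that("disabling remap and smoothing with 2 classes reduces to Otsu in the blob", {
  ph <- make_phantom(phantom_spec(seed = 4))
  fit <- crcd(ph, refine_contour = FALSE)
  proj <- fit$score_image
  cr <- confidence_region(proj, fit$resultant, remap = FALSE, dwt = FALSE,
                          classes = 2, dilate_radius = 6)
  otsu <- binarize(proj, "auto")
  dil <- crcd:::.dilate_disc(fit$resultant$mask, 6)
  expect_identical(cr$mask, otsu & dil)
})
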