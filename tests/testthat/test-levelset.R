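test_that("bounding boxes match the coordinate-scan oracle", {
  m <- matrix(FALSE, 8, 8); m[4, 5] <- TRUE
  expect_equal(unname(bounding_box(m)), c(4, 4, 5, 5))
  expect_equal(unname(bounding_box(matrix(TRUE, 10, 20))), c(1, 10, 1, 20))
  set.seed(21)
  for (i in 1:50) {
    m <- random_mask(14, 11, 0.3)
    if (!any(m)) next
    expect_equal(unname(bounding_box(m)), oracle_bbox(m))
  }
  expect_error(bounding_box(matrix(FALSE, 4, 4)), "empty-selection")
})

test_that("Gaussian kernel is normalized, symmetric, and limits correctly", {
  k <- gaussian_kernel(13, 3)
  expect_equal(dim(k), c(13L, 13L))
  expect_lt(abs(sum(k) - 1), 1e-12)
  expect_equal(k, k[13:1, ])              # reflection symmetric
  expect_equal(k, t(k))
  expect_equal(gaussian_kernel(1, 5), matrix(1))
  # huge sigma -> uniform kernel
  ku <- gaussian_kernel(5, 1e6)
  expect_lt(max(abs(ku - 1 / 25)), 1e-10)
  expect_error(gaussian_kernel(4, 1), "parameter error")
})

test_that("phi initialization partitions the frame at the box", {
  st <- init_phi(c(3, 3, 4, 4), c(8, 8))
  expect_equal(sum(st$phi < 0), 1L)
  expect_equal(st$phi[3, 4], -2)
  # full-extent box: all interior, contour is the image border
  stf <- init_phi(c(1, 8, 1, 8), c(8, 8))
  expect_true(all(stf$phi < 0))
  border <- unique(rbind(cbind(1, 1:8), cbind(8, 1:8),
                         cbind(1:8, 1), cbind(1:8, 8)))
  expect_equal(nrow(stf$contour), nrow(border))
  # sign partitions frame into box and complement
  st2 <- init_phi(c(2, 5, 3, 6), c(9, 9))
  inside <- matrix(FALSE, 9, 9); inside[2:5, 3:6] <- TRUE
  expect_identical(st2$phi < 0, inside)
  expect_error(init_phi(c(0, 3, 1, 3), c(8, 8)), "validation error")
  expect_error(init_phi(c(1, 9, 1, 3), c(8, 8)), "validation error")
})

test_that("fitted means average a constant image to itself", {
  st <- init_phi(c(10, 20, 10, 20), c(30, 30))
  img <- matrix(0.42, 30, 30)
  fm <- rsf_fitted_means(img, st)
  expect_lt(max(abs(fm$f_in - 0.42)), 1e-9)
  expect_lt(max(abs(fm$f_out - 0.42)), 1e-9)
})

test_that("fitted means recover two-level intensities away from the interface", {
  nr <- 60
  img <- matrix(0.1, nr, nr); img[20:40, 20:40] <- 0.9
  st <- init_phi(c(20, 40, 20, 40), c(nr, nr))
  fm <- rsf_fitted_means(img, st)
  # kernel radius 6: check >= 7 px from the interface
  expect_lt(abs(fm$f_in[30, 30] - 0.9), 1e-3)
  expect_lt(abs(fm$f_out[5, 5] - 0.1), 1e-3)
  # kernel size 1 makes the fitted means pointwise
  st1 <- init_phi(c(20, 40, 20, 40), c(nr, nr),
                  params = rsf_params(kernel_size = 3, kernel_sigma = 1e-4))
  fm1 <- rsf_fitted_means(img, st1)
  expect_lt(max(abs(fm1$f_in - img)), 1e-6)
})

test_that("evolution segments a disc and zero iterations is the identity", {
  d <- disc_image()
  st <- init_phi(c(25, 75, 25, 75), c(100, 100))
  st0 <- rsf_evolve(d$image, st, iterations = 0)
  expect_identical(st0$phi, st$phi)
  st <- rsf_evolve(d$image, st, iterations = 400)
  expect_gte(dice(interior_mask(st), d$truth), 0.95)
  # interior is connected and contains the centroid
  lab <- label_components(interior_mask(st), 8)
  expect_equal(length(lab$areas), 1L)
  expect_true(interior_mask(st)[50, 50])
})

test_that("on a constant image the contour never escapes the init box", {
  img <- matrix(0.5, 60, 60)
  st <- init_phi(c(20, 40, 20, 40), c(60, 60))
  st <- rsf_evolve(img, st, iterations = 100)
  inside <- interior_mask(st)
  rad <- (st$params$kernel_size - 1) %/% 2
  allowed <- matrix(FALSE, 60, 60)
  allowed[(20 - rad):(40 + rad), (20 - rad):(40 + rad)] <- TRUE
  expect_true(all(!inside | allowed))
})

test_that("contour extraction matches the neighbour-scan oracle", {
  st <- init_phi(c(2, 5, 2, 5), c(8, 8))
  ct <- extract_contour(st$phi)
  expect_equal(nrow(ct), 12)  # 4x4 box perimeter
  expect_true(all(st$phi[ct] < 0))
  # uniform sign -> empty
  expect_equal(nrow(extract_contour(matrix(1, 5, 5))), 0)
  expect_equal(nrow(extract_contour(matrix(-1, 5, 5))), 0)
  set.seed(8)
  for (i in 1:20) {
    phi <- matrix(rnorm(100), 10, 10)
    a <- extract_contour(phi)
    b <- oracle_contour(phi)
    expect_equal(unname(a[order(a[, 1], a[, 2]), , drop = FALSE]),
                 b[order(b[, 1], b[, 2]), , drop = FALSE])
  }
})

test_that("divergence mid-run is reported with the iteration", {
  d <- disc_image(40, 40, c(20, 20), 8)
  st <- init_phi(c(10, 30, 10, 30), c(40, 40),
                 params = rsf_params(timestep = 1e6))
  expect_error(rsf_evolve(d$image, st, iterations = 50),
               "divergence error.*iteration")
})
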