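make_test_volume <- function(n = 10, offset = 65) {
  grey_volume(array(runif(n * 16 * 16), c(n, 16, 16)), slice_offset = offset)
}

test_that("slice grouping honours source numbering and rejects bad ranges", {
  set.seed(1)
  v <- make_test_volume()
  g <- group_slices(v, list(c(65, 69), c(70, 74)))
  expect_length(g, 2)
  expect_equal(dim(g[[1]]$slices)[1], 5L)
  expect_equal(dim(g[[2]]$slices)[1], 5L)
  expect_equal(g[[1]]$slices[1, , ], v$data[1, , ])
  expect_equal(g[[2]]$slices[1, , ], v$data[6, , ])

  one <- group_slices(v, list(c(65, 74)))
  expect_equal(dim(one[[1]]$slices)[1], 10L)

  expect_error(group_slices(v, list(c(65, 70), c(70, 74))), "overlapping")
  expect_error(group_slices(v, list(c(60, 64))), "outside volume")
  expect_error(group_slices(v, list(c(69, 65))), "start <= end")
})

test_that("pattern blob unions per-slice biggest blobs", {
  # identical slices: union equals any single slice's blob
  base <- matrix(0.1, 16, 16); base[4:8, 4:8] <- 0.9
  vol <- array(rep(base, 3), c(16, 16, 3))
  g <- list(range = c(1, 3), slices = aperm(vol, c(3, 1, 2)))
  p <- pattern_blob(g, adjust_params(0.2, 0.8), threshold = "auto")
  single <- biggest_blob(label_components(binarize(
    adjust_intensity(base, adjust_params(0.2, 0.8)), "auto")))
  expect_identical(p$pattern_blob, single)

  # translated blob: union is a strict superset of any single-slice blob
  sl <- array(0.1, c(3, 16, 16))
  for (s in 1:3) sl[s, 4:8, (3 + s):(7 + s)] <- 0.9
  p2 <- pattern_blob(list(range = c(1, 3), slices = sl), adjust_params(0.2, 0.8))
  expect_gt(sum(p2$pattern_blob), sum(sl[1, , ] > 0.5))

  # a blank slice is skipped, not fatal
  sl2 <- array(0.1, c(2, 16, 16)); sl2[2, 4:8, 4:8] <- 0.9
  p3 <- pattern_blob(list(range = c(1, 2), slices = sl2), adjust_params(0.2, 0.8))
  expect_identical(p3$pattern_blob, sl2[2, , ] > 0.5)
  expect_equal(p3$n_slices_used, 1L)

  # all slices blank -> empty-pattern error
  expect_error(pattern_blob(list(range = c(1, 2),
                                 slices = array(0.1, c(2, 8, 8))),
                            adjust_params(0.2, 0.8)),
               "empty-pattern")
})

test_that("blob fusion is a union with a pixel-count confidence score", {
  a <- matrix(FALSE, 10, 10); a[1:3, 1:4] <- TRUE    # 12 px
  b <- matrix(FALSE, 10, 10); b[6:7, 6:9] <- TRUE    # 8 px, disjoint
  pa <- structure(list(slice_range = c(1, 1), pattern_blob = a,
                       color = "red"), class = "pattern_group")
  pb <- structure(list(slice_range = c(2, 2), pattern_blob = b,
                       color = "green"), class = "pattern_group")
  r <- combine_blobs(list(pa, pb))
  expect_equal(r$confidence_score, 20L)
  expect_identical(r$mask, a | b)
  # idempotence on identical blobs
  expect_equal(combine_blobs(list(pa, pa))$confidence_score, 12L)
  # commutative on the mask
  expect_identical(combine_blobs(list(pb, pa))$mask, r$mask)
  # monotone as patterns are added
  expect_gte(r$confidence_score, combine_blobs(list(pa))$confidence_score)
  # overlay colours each pattern
  expect_equal(r$overlay[1, 1, ], c(1, 0, 0))
  expect_equal(r$overlay[6, 6, ], c(0, 1, 0))
  # shape mismatch
  pc <- structure(list(slice_range = c(3, 3),
                       pattern_blob = matrix(FALSE, 8, 8), color = "blue"),
                  class = "pattern_group")
  expect_error(combine_blobs(list(pa, pc)), "differing shapes")
})

test_that("fusion score matches the elementwise-OR oracle on random masks", {
  set.seed(99)
  for (i in 1:50) {
    a <- random_mask(12, 12); b <- random_mask(12, 12)
    pa <- structure(list(slice_range = c(1, 1), pattern_blob = a,
                         color = "red"), class = "pattern_group")
    pb <- structure(list(slice_range = c(2, 2), pattern_blob = b,
                         color = "green"), class = "pattern_group")
    score <- combine_blobs(list(pa, pb))$confidence_score
    brute <- sum(vapply(seq_along(a), function(k) a[k] || b[k], logical(1)))
    expect_equal(score, brute)
  }
})

test_that("ground-truth overlap decomposition satisfies the set identities", {
  set.seed(3)
  for (i in 1:30) {
    pred <- random_mask(10, 10); truth <- random_mask(10, 10)
    ov <- overlap_with_truth(pred, truth)
    expect_equal(ov$counts[["intersection"]] + ov$counts[["pred_only"]],
                 ov$counts[["prediction"]])
    expect_equal(ov$counts[["intersection"]] + ov$counts[["truth_only"]],
                 ov$counts[["truth"]])
  }
  m <- random_mask(8, 8)
  ov <- overlap_with_truth(m, m)
  expect_equal(ov$counts[["pred_only"]], 0L)
  expect_equal(ov$counts[["truth_only"]], 0L)
  a <- matrix(FALSE, 4, 4); a[1, 1] <- TRUE
  b <- matrix(FALSE, 4, 4); b[4, 4] <- TRUE
  expect_equal(sum(overlap_with_truth(a, b)$intersection), 0L)
  expect_error(overlap_with_truth(a, matrix(FALSE, 5, 5)), "shapes differ")
})
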