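# Confidence-interval transform: from the confidence-score image to the
# confidence region. The whole-image standard deviation and per-quadrant
# means define a +/- 1.96 sigma band per quadrant; pixels are remapped by a
# three-band rule, optionally Haar-smoothed, and classified by multi-level
# Otsu. The final tumour mask is the top intensity class restricted to a
# dilation of the resultant blob.

#' Whole-image (population) standard deviation
#'
#' @param image numeric matrix or array.
#' @return Population standard deviation over all pixels.
#' @export
image_std <- function(image) {
  if (length(image) == 0L) stop("validation error: empty image")
  x <- as.vector(image)
  sqrt(mean((x - mean(x))^2))
}

# Row/col ranges of the four quadrants: split at floor(n/2), extra row/col in
# the bottom/right quadrants. Order: top-left, top-right, bottom-left,
# bottom-right.
.quadrant_ranges <- function(nr, nc) {
  hr <- nr %/% 2L; hc <- nc %/% 2L
  list(tl = list(rows = 1:hr, cols = 1:hc),
       tr = list(rows = 1:hr, cols = (hc + 1L):nc),
       bl = list(rows = (hr + 1L):nr, cols = 1:hc),
       br = list(rows = (hr + 1L):nr, cols = (hc + 1L):nc))
}

#' Per-quadrant means
#'
#' Divides the image into four parts (split at `floor(n/2)` in each
#' dimension; odd dimensions put the extra row/col in the bottom/right parts)
#' and returns the mean of each.
#'
#' @param image 2-D matrix, at least 2 x 2.
#' @return Named numeric vector `(tl, tr, bl, br)`.
#' @export
quadrant_means <- function(image) {
  if (!is.matrix(image) || nrow(image) < 2L || ncol(image) < 2L)
    stop("validation error: image must be at least 2 x 2")
  q <- .quadrant_ranges(nrow(image), ncol(image))
  vapply(q, function(z) mean(image[z$rows, z$cols]), numeric(1))
}

#' Confidence-interval bounds around a mean
#'
#' `A1 = mean - z * sigma`, `A2 = mean + z * sigma` (default `z = 1.96`, the
#' two-sided 95% normal quantile). Vectorized over `mean`.
#'
#' @param mean sub-image mean(s).
#' @param sigma whole-image standard deviation, `>= 0`.
#' @param z interval half-width in sigma units.
#' @return List with `lower` (A1) and `upper` (A2).
#' @export
#' @examples
#' ci_bounds(0.5, 0.1)  # (0.304, 0.696)
ci_bounds <- function(mean, sigma, z = 1.96) {
  if (sigma < 0) stop("parameter error: sigma must be non-negative")
  list(lower = mean - z * sigma, upper = mean + z * sigma)
}

#' Confidence bounds of an image
#'
#' Bundles the quadrant means, the whole-image standard deviation and the
#' per-quadrant interval bounds.
#'
#' @param image 2-D intensity matrix.
#' @param z interval half-width in sigma units (default 1.96).
#' @return Object of class `confidence_bounds`: list with `quadrant_means`,
#'   `sigma`, `lower`, `upper`, `z`.
#' @export
confidence_bounds <- function(image, z = 1.96) {
  qm <- quadrant_means(image)
  s <- image_std(image)
  b <- ci_bounds(qm, s, z)
  structure(list(quadrant_means = qm, sigma = s,
                 lower = b$lower, upper = b$upper, z = z),
            class = "confidence_bounds")
}

#' Remap pixels with the confidence interval
#'
#' Three-band rule per pixel `p` in quadrant `q` with mean `a_q` and lower
#' bound `A1_q`: keep `p` if `p >= a_q`; brighten to `min(1, p + a_q)` if
#' `A1_q <= p < a_q`; assign the mean `a_q` if `p < A1_q`. No pixel value is
#' ever decreased below `min(p, a_q)` and the output stays in `[0, 1]`.
#'
#' @param image 2-D intensity matrix in `[0, 1]`.
#' @param bounds a [confidence_bounds()] object (defaults to the bounds of
#'   `image` itself).
#' @return Remapped image, same shape.
#' @export
remap_pixels <- function(image, bounds = confidence_bounds(image)) {
  if (!inherits(bounds, "confidence_bounds"))
    stop("validation error: 'bounds' must be a confidence_bounds object")
  out <- image
  q <- .quadrant_ranges(nrow(image), ncol(image))
  for (i in seq_along(q)) {
    rows <- q[[i]]$rows; cols <- q[[i]]$cols
    p <- image[rows, cols]
    a <- bounds$quadrant_means[i]
    a1 <- bounds$lower[i]
    r <- p
    mid <- p < a & p >= a1
    r[mid] <- pmin(1, p[mid] + a)
    r[p < a1] <- a
    out[rows, cols] <- r
  }
  out
}

#' Single-level Haar smoothing
#'
#' One level of the 2-D Haar wavelet transform with the detail coefficients
#' zeroed and the inverse transform applied: every 2 x 2 block is replaced by
#' its mean. Odd dimensions are edge-padded internally; output is clipped to
#' `[0, 1]` and has the input shape.
#'
#' @param image 2-D intensity matrix.
#' @return Smoothed image, same shape.
#' @export
dwt_smooth <- function(image) {
  nr <- nrow(image); nc <- ncol(image)
  ri <- if (nr %% 2L) c(seq_len(nr), nr) else seq_len(nr)
  ci <- if (nc %% 2L) c(seq_len(nc), nc) else seq_len(nc)
  x <- image[ri, ci]
  n2 <- nrow(x) %/% 2L; m2 <- ncol(x) %/% 2L
  odd_r <- 2L * seq_len(n2) - 1L; odd_c <- 2L * seq_len(m2) - 1L
  approx <- (x[odd_r, odd_c] + x[odd_r + 1L, odd_c] +
             x[odd_r, odd_c + 1L] + x[odd_r + 1L, odd_c + 1L]) / 4
  rec <- approx[rep(seq_len(n2), each = 2L), rep(seq_len(m2), each = 2L)]
  pmin(pmax(rec[seq_len(nr), seq_len(nc)], 0), 1)
}

#' Multi-level Otsu classification
#'
#' Thresholds maximizing the between-class variance of the 256-bin
#' histogram; pixels are labelled `0 .. classes-1` in ascending intensity
#' order.
#'
#' @param image 2-D intensity matrix in `[0, 1]` with at least `classes`
#'   distinct values.
#' @param classes number of classes (default 3: background, normal tissue,
#'   tumour).
#' @return Integer label matrix.
#' @export
multi_threshold <- function(image, classes = 3L) {
  classes <- as.integer(classes)
  if (classes < 2L) stop("parameter error: classes must be >= 2")
  thr <- .otsu_thresholds(image, classes)
  labels <- matrix(0L, nrow(image), ncol(image))
  for (t in thr) labels <- labels + (image >= t)
  labels
}

#' Transform the score image into the confidence region
#'
#' Full confidence-interval pipeline: whole-image standard deviation and
#' quadrant means -> interval bounds -> pixel remap -> optional Haar
#' smoothing -> multi-level Otsu. The final tumour mask is the top intensity
#' class intersected with a disc dilation of the resultant blob mask.
#'
#' @param image 2-D intensity matrix in `[0, 1]` (the adjusted slice or
#'   score projection).
#' @param resultant a [combine_blobs()] result or a logical blob mask; an
#'   empty mask yields an empty confidence-region mask.
#' @param remap apply the confidence-interval remap (default TRUE).
#' @param dwt apply Haar smoothing (default TRUE).
#' @param classes number of Otsu classes (default 3).
#' @param z interval half-width in sigma units (default 1.96).
#' @param dilate_radius dilation radius in pixels for the blob constraint
#'   (default 6, the 13 x 13 kernel radius).
#' @return Object of class `confidence_region`: list with `remapped`,
#'   `bounds`, `class_labels`, `mask`.
#' @export
confidence_region <- function(image, resultant, remap = TRUE, dwt = TRUE,
                              classes = 3L, z = 1.96, dilate_radius = 6L) {
  blob <- if (inherits(resultant, "resultant_blob")) resultant$mask
          else .as_mask(resultant)
  if (!identical(dim(image), dim(blob)))
    stop("validation error: image and blob shapes differ")
  bounds <- confidence_bounds(image, z)
  remapped <- if (remap) remap_pixels(image, bounds) else image
  smoothed <- if (dwt) dwt_smooth(remapped) else remapped
  labels <- multi_threshold(smoothed, classes)
  top <- labels == max(labels)
  mask <- if (any(blob)) top & .dilate_disc(blob, dilate_radius)
          else blob
  structure(list(remapped = remapped, bounds = bounds,
                 class_labels = labels, mask = mask),
            class = "confidence_region")
}

#' @export
print.confidence_region <- function(x, ...) {
  cat(sprintf("<confidence_region> %d x %d, %d class(es), %d mask pixel(s)\n",
              nrow(x$class_labels), ncol(x$class_labels),
              max(x$class_labels) + 1L, sum(x$mask)))
  cat(sprintf("  sigma %.4f; quadrant means %s\n", x$bounds$sigma,
              paste(sprintf("%.3f", x$bounds$quadrant_means), collapse = " ")))
  invisible(x)
}
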