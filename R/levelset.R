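# Region-scalable-fitting (RSF) level-set contour refinement.
#
# The contour is the zero crossing of a signed function phi (negative inside).
# The data term fits two kernel-weighted local means f_in, f_out around each
# pixel; evolution is explicit gradient descent on the RSF energy with a
# length penalty and a distance-regularization term (no re-initialization).

#' RSF level-set parameters
#'
#' @param kernel_size odd Gaussian kernel width in pixels (default 13, the
#'   low-pass kernel convolved around the resultant blob).
#' @param kernel_sigma Gaussian scale in pixels (default 3).
#' @param lambda_in,lambda_out data-force weights for the inside/outside
#'   fitting residuals (default 1, 1).
#' @param mu distance-regularization weight (default 1).
#' @param nu contour-length weight (default `0.003 * 255^2`, matched to the
#'   0--255 intensity scale the data terms are evaluated on).
#' @param epsilon smoothing width of the regularized Heaviside (default 1).
#' @param timestep explicit Euler step (default 0.1).
#' @param iterations number of evolution steps (default 300; boundary
#'   separation typically needs a few hundred).
#' @return An object of class `rsf_params`.
#' @export
rsf_params <- function(kernel_size = 13L, kernel_sigma = 3.0,
                       lambda_in = 1.0, lambda_out = 1.0,
                       mu = 1.0, nu = 0.003 * 255^2, epsilon = 1.0,
                       timestep = 0.1, iterations = 300L) {
  if (kernel_size %% 2 != 1 || kernel_size < 3)
    stop("parameter error: kernel_size must be odd and >= 3")
  if (kernel_sigma <= 0 || timestep <= 0 || epsilon <= 0)
    stop("parameter error: kernel_sigma, timestep, epsilon must be positive")
  if (iterations < 1) stop("parameter error: iterations must be >= 1")
  structure(list(kernel_size = as.integer(kernel_size),
                 kernel_sigma = kernel_sigma,
                 lambda_in = lambda_in, lambda_out = lambda_out,
                 mu = mu, nu = nu, epsilon = epsilon,
                 timestep = timestep, iterations = as.integer(iterations)),
            class = "rsf_params")
}

#' Tight bounding box of a mask
#'
#' @param mask logical (or 0/1) matrix with at least one set pixel.
#' @return Integer vector `(row_min, row_max, col_min, col_max)`, inclusive,
#'   1-based.
#' @export
bounding_box <- function(mask) {
  mask <- .as_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("empty-selection error: mask has no set pixels")
  c(row_min = min(idx[, 1]), row_max = max(idx[, 1]),
    col_min = min(idx[, 2]), col_max = max(idx[, 2]))
}

#' Normalized Gaussian kernel
#'
#' Square kernel with entries proportional to
#' `exp(-(r^2 + c^2) / (2 sigma^2))`, centred, summing to 1.
#'
#' @param size odd kernel width.
#' @param sigma positive scale.
#' @return `size x size` matrix.
#' @export
#' @examples
#' sum(gaussian_kernel(13, 3))  # 1
gaussian_kernel <- function(size = 13L, sigma = 3.0) {
  if (size %% 2 != 1 || size < 1)
    stop("parameter error: kernel size must be odd and positive")
  if (sigma <= 0) stop("parameter error: sigma must be positive")
  r <- seq_len(size) - (size + 1) / 2
  g <- exp(-r^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# 1-D Gaussian weights (separable form of gaussian_kernel)
.gauss1d <- function(size, sigma) {
  r <- seq_len(size) - (size + 1) / 2
  g <- exp(-r^2 / (2 * sigma^2))
  g / sum(g)
}

# Separable 2-D convolution with symmetric (reflected) boundary padding.
.conv2_sep <- function(x, g) {
  p <- (length(g) - 1L) %/% 2L
  if (p == 0L) return(x * g)
  nr <- nrow(x); nc <- ncol(x)
  ri <- c(p:1, 1:nr, nr:(nr - p + 1L))
  ci <- c(p:1, 1:nc, nc:(nc - p + 1L))
  xp <- x[ri, ]
  out <- matrix(0, nr, nc)
  for (k in seq_along(g)) out <- out + g[k] * xp[(k - 1L) + seq_len(nr), ]
  xp <- out[, ci]
  out <- matrix(0, nr, nc)
  for (k in seq_along(g)) out <- out + g[k] * xp[, (k - 1L) + seq_len(nc)]
  out
}

# Binary dilation by a disc of the given radius (pixels).
.dilate_disc <- function(mask, radius) {
  mask <- .as_mask(mask)
  if (radius < 1) return(mask)
  r <- as.integer(radius)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (dr in -r:r) {
    wid <- floor(sqrt(radius^2 - dr^2))
    rs <- max(1L, 1L - dr):min(nr, nr - dr)
    for (dc in -wid:wid) {
      cs <- max(1L, 1L - dc):min(nc, nc - dc)
      out[rs + dr, cs + dc] <- out[rs + dr, cs + dc] | mask[rs, cs]
    }
  }
  out
}

#' Initialize the level-set function from a bounding box
#'
#' `phi = -c0` inside the (inclusive) box, `+c0` outside; the initial contour
#' is the box perimeter.
#'
#' @param box `(row_min, row_max, col_min, col_max)` from [bounding_box()].
#' @param shape `(rows, cols)` of the slice.
#' @param c0 positive plateau height (default 2).
#' @param params an [rsf_params()] object attached to the state.
#' @return An object of class `level_set_state`: list with `phi`, `params`,
#'   `iteration`, `contour` (matrix of row/col coordinates) and
#'   `energy_trace`.
#' @export
init_phi <- function(box, shape, c0 = 2, params = rsf_params()) {
  box <- as.integer(box)
  if (length(box) != 4L || box[1] > box[2] || box[3] > box[4])
    stop("validation error: malformed bounding box")
  if (box[1] < 1L || box[3] < 1L || box[2] > shape[1] || box[4] > shape[2])
    stop("validation error: box outside the slice")
  phi <- matrix(c0, shape[1], shape[2])
  phi[box[1]:box[2], box[3]:box[4]] <- -c0
  rows <- box[1]:box[2]; cols <- box[3]:box[4]
  ring <- rbind(cbind(box[1], cols), cbind(box[2], cols),
                cbind(rows, box[3]), cbind(rows, box[4]))
  ring <- unique(ring)
  colnames(ring) <- c("row", "col")
  structure(list(phi = phi, params = params, iteration = 0L,
                 contour = ring[order(ring[, 1], ring[, 2]), , drop = FALSE],
                 energy_trace = numeric(0)),
            class = "level_set_state")
}

#' @export
print.level_set_state <- function(x, ...) {
  cat(sprintf("<level_set_state> %d x %d, iteration %d, %d contour pixel(s), %d interior pixel(s)\n",
              nrow(x$phi), ncol(x$phi), x$iteration, nrow(x$contour),
              sum(x$phi < 0)))
  invisible(x)
}

# Regularized Heaviside and its derivative.
.heaviside <- function(phi, eps) 0.5 * (1 + (2 / pi) * atan(phi / eps))
.delta <- function(phi, eps) (eps / pi) / (eps^2 + phi^2)

#' Kernel-weighted local fitted means
#'
#' The RSF fitted means localise the intensity inside and outside the
#' contour: `f_in = K*(H(-phi) I) / K*H(-phi)` and analogously for `f_out`
#' with `H(phi)`, where `H` is the smoothed Heaviside and `*` is convolution
#' with reflected-boundary padding. Denominators are floored at 1e-10.
#'
#' @param image 2-D intensity matrix, same shape as `state$phi`.
#' @param state a [init_phi()] / [rsf_evolve()] state.
#' @return List with matrices `f_in` and `f_out`.
#' @export
rsf_fitted_means <- function(image, state) {
  if (!identical(dim(image), dim(state$phi)))
    stop("validation error: image and phi shapes differ")
  p <- state$params
  g <- .gauss1d(p$kernel_size, p$kernel_sigma)
  h_in <- 1 - .heaviside(state$phi, p$epsilon)
  ki <- .conv2_sep(image, g)
  c1 <- .conv2_sep(h_in * image, g)
  c2 <- .conv2_sep(h_in, g)
  f_in <- c1 / pmax(c2, 1e-10)
  f_out <- (ki - c1) / pmax(1 - c2, 1e-10)
  list(f_in = f_in, f_out = f_out)
}

# Neumann (replicate) boundary pad by one pixel.
.pad1 <- function(x) {
  x <- rbind(x[1, ], x, x[nrow(x), ])
  cbind(x[, 1], x, x[, ncol(x)])
}

# Central-difference gradient, curvature div(grad/|grad|), and 5-point
# Laplacian, all with replicate boundaries.
.grad <- function(x) {
  xp <- .pad1(x)
  n <- nrow(x); m <- ncol(x)
  list(gr = (xp[3:(n + 2), 2:(m + 1)] - xp[1:n, 2:(m + 1)]) / 2,
       gc = (xp[2:(n + 1), 3:(m + 2)] - xp[2:(n + 1), 1:m]) / 2)
}
.div <- function(fr, fc) {
  frp <- .pad1(fr); fcp <- .pad1(fc)
  n <- nrow(fr); m <- ncol(fr)
  (frp[3:(n + 2), 2:(m + 1)] - frp[1:n, 2:(m + 1)]) / 2 +
    (fcp[2:(n + 1), 3:(m + 2)] - fcp[2:(n + 1), 1:m]) / 2
}
.curvature <- function(phi) {
  g <- .grad(phi)
  nrm <- sqrt(g$gr^2 + g$gc^2) + 1e-10
  .div(g$gr / nrm, g$gc / nrm)
}
.laplacian <- function(phi) {
  xp <- .pad1(phi)
  n <- nrow(phi); m <- ncol(phi)
  xp[1:n, 2:(m + 1)] + xp[3:(n + 2), 2:(m + 1)] +
    xp[2:(n + 1), 1:m] + xp[2:(n + 1), 3:(m + 2)] - 4 * phi
}

# Kernel-weighted squared-residual fields e_in/e_out on the 0-255 scale.
# e(x) = I(x)^2 (K*1) - 2 I(x) (K*f) + K*(f^2); K*1 = 1 under reflected
# padding of a normalized kernel.
.rsf_residuals <- function(img255, f_in, f_out, g) {
  e_in <- img255^2 - 2 * img255 * .conv2_sep(f_in, g) + .conv2_sep(f_in^2, g)
  e_out <- img255^2 - 2 * img255 * .conv2_sep(f_out, g) + .conv2_sep(f_out^2, g)
  list(e_in = e_in, e_out = e_out)
}

#' RSF energy of a state
#'
#' Data term (kernel-weighted squared fitting residuals, weighted by the
#' smoothed region indicators) plus `nu` times the contour-length surrogate
#' `sum(delta(phi) |grad phi|)`. Intensities enter on the 0--255 scale, the
#' scale the default weights are calibrated to.
#'
#' @param image 2-D intensity matrix in `[0, 1]`.
#' @param state a level-set state.
#' @return Scalar energy.
#' @export
rsf_energy <- function(image, state) {
  p <- state$params
  g <- .gauss1d(p$kernel_size, p$kernel_sigma)
  .rsf_energy_of(image * 255, state$phi, p, g)
}

.rsf_energy_of <- function(img255, phi, p, g) {
  h_in <- 1 - .heaviside(phi, p$epsilon)
  c1 <- .conv2_sep(h_in * img255, g)
  c2 <- .conv2_sep(h_in, g)
  f_in <- c1 / pmax(c2, 1e-10)
  f_out <- (.conv2_sep(img255, g) - c1) / pmax(1 - c2, 1e-10)
  e <- .rsf_residuals(img255, f_in, f_out, g)
  gd <- .grad(phi)
  len <- sum(.delta(phi, p$epsilon) * sqrt(gd$gr^2 + gd$gc^2))
  sum(p$lambda_in * e$e_in * h_in + p$lambda_out * e$e_out * (1 - h_in)) +
    p$nu * len
}

#' Evolve the RSF level set
#'
#' Runs explicit-Euler updates of the level-set function: the data force
#' `delta(phi) (lambda_in e_in - lambda_out e_out)` (gradient descent on the
#' region-scalable fitting energy; `phi < 0` is the inside), the length force
#' `nu delta(phi) curvature(phi)` and the distance regularization
#' `mu (laplacian(phi) - curvature(phi))`. For speed the evolution runs on
#' the slice restricted to a margin of twice the kernel radius around the
#' current interior and is pasted back into full-frame coordinates.
#' Intensities are mapped to the 0--255 scale internally so the default
#' weights are balanced. The energy is recorded every 10 iterations in
#' `energy_trace`.
#'
#' @param image 2-D intensity matrix in `[0, 1]`.
#' @param state a [init_phi()] state (or the result of a previous call).
#' @param iterations number of steps; defaults to `state$params$iterations`.
#'   Zero returns the state unchanged.
#' @return The updated `level_set_state` with refreshed contour.
#' @export
rsf_evolve <- function(image, state, iterations = NULL) {
  if (!identical(dim(image), dim(state$phi)))
    stop("validation error: image and phi shapes differ")
  p <- state$params
  iters <- if (is.null(iterations)) p$iterations else as.integer(iterations)
  if (iters == 0L) return(state)
  rad <- (p$kernel_size - 1L) %/% 2L
  margin <- 2L * rad
  inside <- state$phi < 0
  if (!any(inside))
    stop("validation error: phi has no interior region to evolve")
  bb <- bounding_box(inside)
  r0 <- max(1L, bb[1] - margin); r1 <- min(nrow(image), bb[2] + margin)
  c0 <- max(1L, bb[3] - margin); c1 <- min(ncol(image), bb[4] + margin)
  phi <- state$phi[r0:r1, c0:c1]
  img255 <- image[r0:r1, c0:c1] * 255
  g <- .gauss1d(p$kernel_size, p$kernel_sigma)
  ki <- .conv2_sep(img255, g)
  trace <- state$energy_trace
  for (it in seq_len(iters)) {
    h_in <- 1 - .heaviside(phi, p$epsilon)
    c1m <- .conv2_sep(h_in * img255, g)
    c2m <- .conv2_sep(h_in, g)
    f_in <- c1m / pmax(c2m, 1e-10)
    f_out <- (ki - c1m) / pmax(1 - c2m, 1e-10)
    e <- .rsf_residuals(img255, f_in, f_out, g)
    dlt <- .delta(phi, p$epsilon)
    kap <- .curvature(phi)
    dphi <- dlt * (p$lambda_in * e$e_in - p$lambda_out * e$e_out) +
      p$nu * dlt * kap +
      p$mu * (.laplacian(phi) - kap)
    phi <- phi + p$timestep * dphi
    if (any(!is.finite(phi)))
      stop("divergence error: non-finite phi at iteration ",
           state$iteration + it)
    if (it %% 10L == 0L)
      trace <- c(trace, .rsf_energy_of(img255, phi, p, g))
  }
  full <- state$phi
  full[r0:r1, c0:c1] <- phi
  state$phi <- full
  state$iteration <- state$iteration + iters
  state$energy_trace <- trace
  state$contour <- extract_contour(state)
  state
}

#' Extract the zero-level contour
#'
#' Contour pixels are interior pixels (`phi < 0`) with at least one
#' 4-neighbour of non-negative `phi`; the set is empty iff `phi` has uniform
#' sign.
#'
#' @param state a level-set state (or a bare `phi` matrix).
#' @return Matrix of `(row, col)` coordinates, ordered by row then column.
#' @export
extract_contour <- function(state) {
  phi <- if (is.matrix(state)) state else state$phi
  neg <- phi < 0
  nonneg <- !neg
  nr <- nrow(phi); nc <- ncol(phi)
  touch <- matrix(FALSE, nr, nc)
  touch[-1, ] <- touch[-1, ] | nonneg[-nr, ]
  touch[-nr, ] <- touch[-nr, ] | nonneg[-1, ]
  touch[, -1] <- touch[, -1] | nonneg[, -nc]
  touch[, -nc] <- touch[, -nc] | nonneg[, -1]
  idx <- which(neg & touch, arr.ind = TRUE)
  colnames(idx) <- c("row", "col")
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Interior mask of a level-set state
#'
#' @param state a level-set state.
#' @return Logical mask of pixels with `phi < 0`.
#' @export
interior_mask <- function(state) state$phi < 0
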