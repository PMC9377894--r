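#' Intensity-adjustment parameters
#'
#' Linear window-stretch used to separate bright (enhancing) tumour tissue
#' from normal tissue before blob detection. Intensities in the window
#' `[low_in, high_in]` are mapped linearly onto `[0, 1]` via
#' `alpha * x + beta` with `alpha = 1/(high_in - low_in)` and
#' `beta = -low_in * alpha`; values outside the window are clipped. The
#' defaults 0.36--0.78 are the window in which enhancing-tumour intensities
#' concentrate on T1-weighted acquisitions.
#'
#' @param low_in,high_in window endpoints in `[0, 1]`, `low_in < high_in`.
#' @return An object of class `adjust_params` with fields `low_in`,
#'   `high_in`, `alpha`, `beta`.
#' @export
#' @examples
#' p <- adjust_params()
#' adjust_intensity(matrix(c(0.36, 0.57, 0.78, 0.1), 2), p)
adjust_params <- function(low_in = 0.36, high_in = 0.78) {
  if (!is.numeric(low_in) || !is.numeric(high_in) ||
      low_in < 0 || high_in > 1 || low_in >= high_in)
    stop("parameter error: need 0 <= low_in < high_in <= 1")
  alpha <- 1 / (high_in - low_in)
  structure(list(low_in = low_in, high_in = high_in,
                 alpha = alpha, beta = -low_in * alpha),
            class = "adjust_params")
}

#' Contrast-adjust a slice
#'
#' Applies the linear window stretch of [adjust_params()] elementwise:
#' `clip(alpha * x + beta, 0, 1)`. Weakly monotone in the input, identity for
#' the full window `(0, 1)`.
#'
#' @param slice 2-D intensity matrix with values in `[0, 1]`.
#' @param params an [adjust_params()] object.
#' @return The adjusted slice, same shape, values in `[0, 1]`.
#' @export
adjust_intensity <- function(slice, params = adjust_params()) {
  if (!inherits(params, "adjust_params"))
    stop("parameter error: 'params' must be an adjust_params object")
  if (min(slice) < 0 || max(slice) > 1)
    stop("validation error: slice intensities outside [0, 1]")
  pmin(pmax(params$alpha * slice + params$beta, 0), 1)
}
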