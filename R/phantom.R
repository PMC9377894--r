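# Seeded synthetic MRI-like phantom: dark background, elliptical "brain" of
# textured tissue, a bright tumour disc with an intensity-falloff rim
# (emulating an enhancing core), per-slice centre drift split into two
# pattern groups, and additive Gaussian noise. Every pipeline stage is
# testable against the known truth masks without clinical data.

#' Phantom specification
#'
#' Defaults describe a 10-slice stack mimicking the tumour-visible portion of
#' an axial acquisition (source numbering 65--74, two pattern groups of 5
#' slices). The tumour centre drifts 1 px per slice along the columns in the
#' first group and along the rows in the second (the direction flip makes
#' the fused blob a strict superset of any single-slice blob).
#'
#' @param shape `(slices, rows, cols)`, default `c(10, 128, 128)`.
#' @param tumour_center `(row, col)` of the tumour on the first slice.
#' @param tumour_radius core disc radius in pixels.
#' @param core_intensity enhancing-core intensity (default 0.85).
#' @param rim_width rim thickness in pixels; intensity falls linearly from
#'   the core to the tissue level across the rim.
#' @param tissue_intensity brain-tissue intensity (default 0.45).
#' @param background_intensity background level (default 0.05).
#' @param drift_per_slice centre translation per slice in pixels.
#' @param pattern_split 1-based slice index (within the stack) at which the
#'   drift direction flips and the second pattern group starts; defaults to
#'   the slice after the midpoint (slice 6 of a 10-slice stack).
#' @param noise_sigma additive Gaussian noise s.d. (default 0.02).
#' @param seed integer RNG seed.
#' @param slice_offset source number of the first slice (default 65).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(10L, 128L, 128L),
                         tumour_center = c(64, 64),
                         tumour_radius = 15,
                         core_intensity = 0.85,
                         rim_width = 3,
                         tissue_intensity = 0.45,
                         background_intensity = 0.05,
                         drift_per_slice = 1,
                         pattern_split = NULL,
                         noise_sigma = 0.02,
                         seed = 1L,
                         slice_offset = 65L) {
  if (!(core_intensity > tissue_intensity &&
        tissue_intensity > background_intensity))
    stop("spec error: need core > tissue > background intensity")
  if (any(c(core_intensity, tissue_intensity, background_intensity) < 0) ||
      core_intensity > 1)
    stop("spec error: intensities must lie in [0, 1]")
  if (is.null(pattern_split)) pattern_split <- shape[1] %/% 2L + 1L
  if (pattern_split < 2L || pattern_split > shape[1])
    stop("spec error: pattern_split must lie inside the stack")
  structure(list(shape = as.integer(shape), tumour_center = tumour_center,
                 tumour_radius = tumour_radius,
                 core_intensity = core_intensity, rim_width = rim_width,
                 tissue_intensity = tissue_intensity,
                 background_intensity = background_intensity,
                 drift_per_slice = drift_per_slice,
                 pattern_split = as.integer(pattern_split),
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 slice_offset = as.integer(slice_offset)),
            class = "phantom_spec")
}

# Per-slice tumour centres: group 1 drifts along columns, group 2 along rows.
.phantom_centres <- function(spec) {
  n <- spec$shape[1]
  t(vapply(seq_len(n), function(s) {
    if (s < spec$pattern_split)
      spec$tumour_center + c(0, (s - 1) * spec$drift_per_slice)
    else
      spec$tumour_center + c((s - spec$pattern_split + 1) *
                               spec$drift_per_slice, 0)
  }, numeric(2)))
}

# Run expr with a fixed seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic phantom volume
#'
#' @param spec a [phantom_spec()].
#' @return Object of class `crcd_phantom`: list with `volume` (a
#'   [grey_volume()]), `truth` (a [mask_volume()], tumour disc plus rim per
#'   slice), `pattern_ranges` (the two source-numbered slice ranges) and
#'   `spec`. Identical specs (including seed) produce bit-identical output.
#' @export
#' @examples
#' ph <- make_phantom(phantom_spec(seed = 7))
#' ph$pattern_ranges
make_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec"))
    stop("spec error: 'spec' must be a phantom_spec")
  n <- spec$shape[1]; nr <- spec$shape[2]; nc <- spec$shape[3]
  centres <- .phantom_centres(spec)
  reach <- spec$tumour_radius + spec$rim_width
  if (any(centres[, 1] - reach < 1) || any(centres[, 1] + reach > nr) ||
      any(centres[, 2] - reach < 1) || any(centres[, 2] + reach > nc))
    stop("spec error: tumour leaves the frame on some slice")
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ell <- ((rows - (nr + 1) / 2) / (0.44 * nr))^2 +
         ((cols - (nc + 1) / 2) / (0.38 * nc))^2 <= 1
  vol <- array(0, spec$shape)
  tru <- array(0L, spec$shape)
  noise <- if (spec$noise_sigma > 0)
    .with_seed(spec$seed,
               array(stats::rnorm(n * nr * nc, 0, spec$noise_sigma),
                     spec$shape))
  else array(0, spec$shape)
  for (s in seq_len(n)) {
    d <- sqrt((rows - centres[s, 1])^2 + (cols - centres[s, 2])^2)
    img <- matrix(spec$background_intensity, nr, nc)
    img[ell] <- spec$tissue_intensity
    rim <- d > spec$tumour_radius & d <= reach
    img[rim] <- spec$core_intensity -
      (d[rim] - spec$tumour_radius) / spec$rim_width *
        (spec$core_intensity - spec$tissue_intensity)
    img[d <= spec$tumour_radius] <- spec$core_intensity
    vol[s, , ] <- pmin(pmax(img + noise[s, , ], 0), 1)
    tru[s, , ] <- as.integer(d <= reach)
  }
  lo <- spec$slice_offset
  ranges <- list(c(lo, lo + spec$pattern_split - 2L),
                 c(lo + spec$pattern_split - 1L, lo + n - 1L))
  structure(list(volume = grey_volume(vol, slice_offset = lo,
                                      source_path = "synthetic phantom"),
                 truth = mask_volume(tru, slice_offset = lo),
                 pattern_ranges = ranges, spec = spec),
            class = "crcd_phantom")
}

#' @export
print.crcd_phantom <- function(x, ...) {
  cat(sprintf("<crcd_phantom> %d slice(s) of %d x %d, seed %d\n",
              x$spec$shape[1], x$spec$shape[2], x$spec$shape[3], x$spec$seed))
  cat("  pattern ranges:",
      paste(vapply(x$pattern_ranges,
                   function(r) paste0(r[1], ":", r[2]), ""), collapse = ", "),
      "\n")
  invisible(x)
}

#' Union of the per-slice truth masks
#'
#' The fused resultant blob lives in one 2-D plane (slices are
#' co-registered), so the matching ground truth for the final mask is the
#' pixelwise union of the per-slice truth discs.
#'
#' @param phantom a [make_phantom()] result.
#' @return Logical `rows x cols` mask.
#' @export
phantom_truth_union <- function(phantom) {
  apply(phantom$truth$data, c(2, 3), max) > 0
}

#' Tiny worked example with frozen expected intermediates
#'
#' An 8 x 8 slice with hand-chosen values, together with the expected
#' outputs of binarize (threshold 0.5), component labelling, biggest-blob
#' selection, quadrant means, interval bounds and the pixel remap. The
#' expected values were computed once with independent brute-force oracles
#' (flood fill, coordinate scans, direct arithmetic) and are frozen here.
#'
#' @return List with `slice`, `threshold`, `mask`, `labels`, `areas`,
#'   `biggest_label`, `quadrant_means`, `sigma`, `lower`, `upper`,
#'   `remapped`, `truth`, `dice`.
#' @export
make_worked_example <- function() {
  slice <- matrix(0.1, 8, 8)
  slice[2:4, 2:4] <- 0.9   # main blob (9 px)
  slice[6:7, 6:7] <- 0.8   # secondary blob (4 px)
  slice[1, 8] <- 0.7       # isolated bright pixel
  slice[5, 1] <- 0.3
  slice[8, 1] <- 0.2

  mask <- slice >= 0.5
  labels <- matrix(0L, 8, 8)
  labels[1, 8] <- 1L       # first in raster order
  labels[2:4, 2:4] <- 2L
  labels[6:7, 6:7] <- 3L

  qm <- c(tl = 0.55, tr = 0.1375, bl = 0.11875, br = 0.275)
  sigma <- 0.3130892881331937  # sqrt(10.95/64 - (17.3/64)^2), two-pass oracle
  truth <- matrix(FALSE, 8, 8)
  truth[2:4, 2:5] <- TRUE  # 12 px, overlapping the 9-px blob

  # per-pixel remap oracle output, column-major (all A1 < 0 here, so the
  # keep and brighten branches are exercised; the assign-mean branch needs
  # p < A1 and is checked separately with explicit bounds)
  remapped <- matrix(c(
    0.65, 0.65, 0.65, 0.65, 0.3, 0.21875, 0.21875, 0.2,
    0.65, 0.9, 0.9, 0.9, 0.21875, 0.21875, 0.21875, 0.21875,
    0.65, 0.9, 0.9, 0.9, 0.21875, 0.21875, 0.21875, 0.21875,
    0.65, 0.9, 0.9, 0.9, 0.21875, 0.21875, 0.21875, 0.21875,
    0.2375, 0.2375, 0.2375, 0.2375, 0.375, 0.375, 0.375, 0.375,
    0.2375, 0.2375, 0.2375, 0.2375, 0.375, 0.8, 0.8, 0.375,
    0.2375, 0.2375, 0.2375, 0.2375, 0.375, 0.8, 0.8, 0.375,
    0.7, 0.2375, 0.2375, 0.2375, 0.375, 0.375, 0.375, 0.375), 8, 8)

  list(slice = slice, threshold = 0.5, mask = mask, labels = labels,
       areas = c(`1` = 1L, `2` = 9L, `3` = 4L), biggest_label = 2L,
       quadrant_means = qm, sigma = sigma,
       lower = qm - 1.96 * sigma, upper = qm + 1.96 * sigma,
       remapped = remapped,
       truth = truth, dice = 18 / 21)
}
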