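#' Confidence-region contour detection
#'
#' Fits the full tumour region-extraction pipeline to a greyscale slice
#' stack: per-slice intensity adjustment, Otsu binarization, 8-connected
#' biggest-blob selection, per-pattern fusion of the blobs into the
#' resultant blob (confidence score), RSF level-set refinement of the
#' contour from the blob's bounding box, and the confidence-interval
#' transform (quadrant means, +/- `z` sigma band, optional Haar smoothing,
#' multi-level Otsu) producing the final confidence-region mask.
#'
#' The fusion plane is 2-D: slices are assumed co-registered, and the score
#' image the contour and confidence stages see is the pixelwise maximum of
#' the adjusted slices (the brightest evidence at each pixel across the
#' stack).
#'
#' @param volume a [grey_volume()], a [make_phantom()] result, or a 3-D
#'   array in `[0, 1]`.
#' @param patterns list of inclusive `(start, end)` slice ranges in source
#'   numbering, one per intensity pattern; default one range covering the
#'   whole stack. A [make_phantom()] input supplies its own ranges.
#' @param low_in,high_in intensity-adjustment window (defaults 0.36, 0.78).
#' @param threshold per-slice binarization threshold, numeric or `"auto"`.
#' @param connectivity blob connectivity, 4 or 8 (default 8).
#' @param rsf an [rsf_params()] object.
#' @param refine_contour run the RSF evolution (default TRUE); when FALSE
#'   the contour stays at the bounding-box initialization.
#' @param remap,dwt,classes,z confidence-stage options, see
#'   [confidence_region()].
#' @param verbose log stage progress via `message()`.
#' @return Object of class `crcd`: list with `call`, `patterns` (list of
#'   [pattern_blob()] results), `resultant` ([combine_blobs()] output),
#'   `score_image` (adjusted projection), `levelset` (final
#'   `level_set_state` or NULL), `region` ([confidence_region()] output),
#'   `mask` (final logical tumour mask) and `params`.
#' @seealso [eval_report()] to score the mask against a ground truth,
#'   [make_phantom()] for synthetic inputs.
#' @export
#' @examples
#' ph <- make_phantom(phantom_spec(seed = 3))
#' fit <- crcd(ph, rsf = rsf_params(iterations = 30))
#' fit
#' eval_report(fit$mask, phantom_truth_union(ph))
crcd <- function(volume, patterns = NULL,
                 low_in = 0.36, high_in = 0.78,
                 threshold = "auto", connectivity = 8,
                 rsf = rsf_params(), refine_contour = TRUE,
                 remap = TRUE, dwt = TRUE, classes = 3L, z = 1.96,
                 verbose = FALSE) {
  cl <- match.call()
  if (inherits(volume, "crcd_phantom")) {
    if (is.null(patterns)) patterns <- volume$pattern_ranges
    volume <- volume$volume
  }
  if (is.array(volume) && !inherits(volume, "grey_volume"))
    volume <- grey_volume(volume)
  if (!inherits(volume, "grey_volume"))
    stop("validation error: 'volume' must be a grey_volume or 3-D array")
  if (is.null(patterns))
    patterns <- list(c(volume$slice_offset,
                       volume$slice_offset + n_slices(volume) - 1L))
  adj <- adjust_params(low_in, high_in)
  say <- function(...) if (verbose) message("crcd: ", ...)

  say("grouping ", n_slices(volume), " slice(s) into ",
      length(patterns), " pattern(s)")
  groups <- group_slices(volume, patterns)
  pats <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    col <- .PATTERN_PALETTE[(i - 1L) %% length(.PATTERN_PALETTE) + 1L]
    pats[[i]] <- pattern_blob(groups[[i]], params = adj,
                              threshold = threshold,
                              connectivity = connectivity, color = col)
    say("pattern ", i, " (slices ", groups[[i]]$range[1], ":",
        groups[[i]]$range[2], "): blob of ",
        sum(pats[[i]]$pattern_blob), " px")
  }
  resultant <- combine_blobs(pats)
  say("confidence score ", resultant$confidence_score, " px")

  # score image: brightest adjusted evidence per pixel across the stack
  proj <- adjust_intensity(volume$data[1, , ], adj)
  if (n_slices(volume) > 1L)
    for (s in 2:n_slices(volume))
      proj <- pmax(proj, adjust_intensity(volume$data[s, , ], adj))

  box <- bounding_box(resultant$mask)
  state <- init_phi(box, dim(proj), params = rsf)
  if (refine_contour) {
    say("RSF evolution, ", rsf$iterations, " iteration(s)")
    state <- rsf_evolve(proj, state)
  }

  rad <- (rsf$kernel_size - 1L) %/% 2L
  region <- confidence_region(proj, resultant, remap = remap, dwt = dwt,
                              classes = classes, z = z, dilate_radius = rad)
  say("confidence-region mask ", sum(region$mask), " px")

  structure(list(call = cl,
                 slice_offset = volume$slice_offset,
                 n_slices = n_slices(volume),
                 patterns = pats, resultant = resultant,
                 score_image = proj, levelset = state,
                 region = region, mask = region$mask,
                 params = list(adjust = adj, threshold = threshold,
                               connectivity = connectivity, rsf = rsf,
                               remap = remap, dwt = dwt, classes = classes,
                               z = z)),
            class = "crcd")
}

#' @export
print.crcd <- function(x, ...) {
  cat("Confidence-region contour detection\n")
  cat(sprintf("  %d slice(s) (%d:%d), %d pattern(s)\n", x$n_slices,
              x$slice_offset, x$slice_offset + x$n_slices - 1L,
              length(x$patterns)))
  cat(sprintf("  confidence score: %d px (resultant blob)\n",
              x$resultant$confidence_score))
  cat(sprintf("  final confidence-region mask: %d px\n", sum(x$mask)))
  invisible(x)
}

#' @export
summary.crcd <- function(object, ...) {
  s <- list(
    n_slices = object$n_slices,
    patterns = lapply(object$patterns, function(p)
      list(range = p$slice_range, area = sum(p$pattern_blob),
           color = p$color)),
    confidence_score = object$resultant$confidence_score,
    bounding_box = bounding_box(object$resultant$mask),
    rsf_iterations = object$levelset$iteration,
    rsf_energy = utils::tail(object$levelset$energy_trace, 1),
    contour_pixels = nrow(object$levelset$contour),
    sigma = object$region$bounds$sigma,
    quadrant_means = object$region$bounds$quadrant_means,
    mask_area = sum(object$mask))
  class(s) <- "summary.crcd"
  s
}

#' @export
print.summary.crcd <- function(x, ...) {
  cat("CRCD fit summary\n")
  for (i in seq_along(x$patterns)) {
    p <- x$patterns[[i]]
    cat(sprintf("  pattern %d: slices %s:%s, blob %d px (%s)\n", i,
                p$range[1], p$range[2], p$area, p$color))
  }
  cat(sprintf("  confidence score %d px; bounding box rows %d:%d cols %d:%d\n",
              x$confidence_score, x$bounding_box[1], x$bounding_box[2],
              x$bounding_box[3], x$bounding_box[4]))
  cat(sprintf("  RSF: %d iteration(s), %d contour px%s\n",
              x$rsf_iterations, x$contour_pixels,
              if (length(x$rsf_energy))
                sprintf(", final energy %.4g", x$rsf_energy) else ""))
  cat(sprintf("  confidence interval: sigma %.4f, quadrant means %s\n",
              x$sigma, paste(sprintf("%.3f", x$quadrant_means),
                             collapse = " ")))
  cat(sprintf("  final mask %d px\n", x$mask_area))
  invisible(x)
}

#' Plot a CRCD fit
#'
#' Four panels: score image, RGB pattern overlay, score image with the RSF
#' contour, and the final confidence-region mask.
#'
#' @param x a [crcd()] fit.
#' @param ... ignored.
#' @export
plot.crcd <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  .show_img <- function(img, main) {
    graphics::image(t(img[nrow(img):1, ]), axes = FALSE, main = main,
                    col = grDevices::gray.colors(64, 0, 1), useRaster = TRUE)
  }
  .show_img(x$score_image, "score image")
  ov <- x$resultant$overlay
  graphics::plot(grDevices::as.raster(ov), main = "pattern overlay")
  .show_img(x$score_image, "RSF contour")
  ct <- x$levelset$contour
  if (nrow(ct)) {
    nr <- nrow(x$score_image); nc <- ncol(x$score_image)
    graphics::points((ct[, 2] - 1) / (nc - 1), (nr - ct[, 1]) / (nr - 1),
                     col = "red", pch = ".", cex = 2)
  }
  .show_img(x$mask * 1, "confidence region")
  invisible(x)
}
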