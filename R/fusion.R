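# Pattern grouping of slices and fusion of per-pattern biggest blobs into the
# resultant blob (the confidence-score image).

# Deterministic provenance palette, assigned by pattern order.
.PATTERN_PALETTE <- c("red", "green", "blue", "yellow", "magenta", "cyan",
                      "orange", "purple")

#' Group slices into intensity patterns
#'
#' Splits a volume into user-supplied runs of consecutive slices that share a
#' visually similar tumour intensity structure (e.g. slices 65--69 vs 70--74
#' of a BraTS acquisition). Ranges use source numbering and must be pairwise
#' disjoint and inside the volume.
#'
#' @param volume a [grey_volume()].
#' @param ranges list of inclusive `(start, end)` pairs in source numbering.
#' @return List of groups; each group is a list with `range` and `slices`
#'   (a `slices x rows x cols` array).
#' @export
#' @examples
#' v <- grey_volume(array(runif(10 * 8 * 8), c(10, 8, 8)), slice_offset = 65)
#' g <- group_slices(v, list(c(65, 69), c(70, 74)))
#' vapply(g, function(x) dim(x$slices)[1], integer(1))
group_slices <- function(volume, ranges) {
  if (!inherits(volume, "grey_volume"))
    stop("validation error: 'volume' must be a grey_volume")
  if (!length(ranges)) stop("parameter error: at least one range required")
  lo <- volume$slice_offset
  hi <- lo + n_slices(volume) - 1L
  covered <- integer(0)
  out <- vector("list", length(ranges))
  for (i in seq_along(ranges)) {
    rg <- as.integer(ranges[[i]])
    if (length(rg) != 2L || rg[1] > rg[2])
      stop("parameter error: range must be (start, end) with start <= end")
    if (rg[1] < lo || rg[2] > hi)
      stop("parameter error: range ", rg[1], ":", rg[2],
           " outside volume slices ", lo, ":", hi)
    idx <- seq.int(rg[1], rg[2])
    if (any(idx %in% covered))
      stop("parameter error: overlapping slice ranges")
    covered <- c(covered, idx)
    out[[i]] <- list(range = rg,
                     slices = volume$data[idx - lo + 1L, , , drop = FALSE])
  }
  out
}

#' Biggest blob of a pattern of slices
#'
#' Runs adjust -> binarize -> label -> biggest-blob on every slice of the
#' group and unions the per-slice biggest blobs into the pattern blob. Slices
#' on which thresholding finds no component (e.g. blank slices) are skipped;
#' if every slice is empty the pattern is an error.
#'
#' @param group one element of [group_slices()] output (or a
#'   `slices x rows x cols` array).
#' @param params an [adjust_params()] object.
#' @param threshold per-slice threshold, numeric or `"auto"` (Otsu).
#' @param connectivity 4 or 8.
#' @param color provenance colour for overlays (any R colour).
#' @return An object of class `pattern_group`: list with `slice_range`,
#'   `pattern_blob` (logical mask), `color`, `n_slices_used`.
#' @export
pattern_blob <- function(group, params = adjust_params(), threshold = "auto",
                         connectivity = 8, color = "red") {
  if (is.array(group) && length(dim(group)) == 3L)
    group <- list(range = c(NA_integer_, NA_integer_), slices = group)
  slices <- group$slices
  n <- dim(slices)[1]
  if (is.null(n) || n < 1L) stop("validation error: empty slice group")
  acc <- NULL
  used <- 0L
  for (s in seq_len(n)) {
    blob <- tryCatch({
      adj <- adjust_intensity(slices[s, , ], params)
      biggest_blob(label_components(binarize(adj, threshold), connectivity))
    }, error = function(e) NULL)
    if (is.null(blob)) next
    acc <- if (is.null(acc)) blob else acc | blob
    used <- used + 1L
  }
  if (is.null(acc))
    stop("empty-pattern error: no slice in the group produced a component")
  structure(list(slice_range = group$range, pattern_blob = acc,
                 color = color, n_slices_used = used),
            class = "pattern_group")
}

#' Fuse pattern blobs into the resultant blob
#'
#' The resultant biggest blob is the pixelwise union of the per-pattern
#' blobs; its pixel count is the confidence score. An RGB overlay colours
#' each pattern's pixels with its provenance colour (later patterns overwrite
#' earlier ones on overlap).
#'
#' @param patterns list of [pattern_blob()] results (colours are filled from
#'   a fixed palette when missing).
#' @return An object of class `resultant_blob`: list with `mask` (logical),
#'   `per_pattern`, `overlay` (`rows x cols x 3` array in `[0,1]`) and
#'   `confidence_score` (foreground pixel count).
#' @export
combine_blobs <- function(patterns) {
  if (inherits(patterns, "pattern_group")) patterns <- list(patterns)
  if (!length(patterns)) stop("validation error: at least one pattern required")
  shp <- dim(patterns[[1]]$pattern_blob)
  for (p in patterns)
    if (!identical(dim(p$pattern_blob), shp))
      stop("validation error: pattern blobs have differing shapes")
  mask <- matrix(FALSE, shp[1], shp[2])
  overlay <- array(0, c(shp, 3L))
  for (i in seq_along(patterns)) {
    p <- patterns[[i]]
    col <- p$color
    if (is.null(col) || is.na(col))
      col <- .PATTERN_PALETTE[(i - 1L) %% length(.PATTERN_PALETTE) + 1L]
    patterns[[i]]$color <- col
    rgb <- grDevices::col2rgb(col)[, 1] / 255
    b <- p$pattern_blob
    mask <- mask | b
    for (ch in 1:3) {
      plane <- overlay[, , ch]
      plane[b] <- rgb[ch]
      overlay[, , ch] <- plane
    }
  }
  structure(list(mask = mask, per_pattern = patterns, overlay = overlay,
                 confidence_score = sum(mask)),
            class = "resultant_blob")
}

#' @export
print.resultant_blob <- function(x, ...) {
  cat(sprintf("<resultant_blob> %d pattern(s), confidence score %d pixel(s)\n",
              length(x$per_pattern), x$confidence_score))
  invisible(x)
}

#' Overlap of a prediction with ground truth
#'
#' Decomposes a predicted mask and a ground-truth mask into intersection,
#' prediction-only and truth-only parts, with pixel counts. `|intersection| +
#' |pred_only| = |prediction|` and symmetrically for truth.
#'
#' @param resultant a [combine_blobs()] result or a logical mask.
#' @param truth logical (or 0/1) ground-truth mask, same shape.
#' @return List with masks `intersection`, `pred_only`, `truth_only` and a
#'   named `counts` vector.
#' @export
overlap_with_truth <- function(resultant, truth) {
  pred <- if (inherits(resultant, "resultant_blob")) resultant$mask
          else .as_mask(resultant)
  truth <- .as_mask(truth)
  if (!identical(dim(pred), dim(truth)))
    stop("validation error: prediction and truth shapes differ")
  inter <- pred & truth
  list(intersection = inter,
       pred_only = pred & !truth,
       truth_only = truth & !pred,
       counts = c(intersection = sum(inter),
                  pred_only = sum(pred & !truth),
                  truth_only = sum(truth & !pred),
                  prediction = sum(pred),
                  truth = sum(truth)))
}
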