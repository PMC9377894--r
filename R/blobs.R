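# Histogram-based thresholding and connected-component (blob) analysis.
# Masks are logical rows x cols matrices throughout.

.NBINS <- 256L

# 256-bin histogram of intensities in [0,1]; bin i covers [ (i-1)/256, i/256 )
# with 1.0 in the last bin.
.hist256 <- function(x) {
  b <- pmin(floor(as.vector(x) * .NBINS), .NBINS - 1L)
  tabulate(b + 1L, nbins = .NBINS)
}

# Exhaustive multi-level Otsu: thresholds (k-1 of them, on the [0,1] scale)
# maximizing the between-class variance, i.e. sum_j w_j * m_j^2 for class
# probabilities w_j and class means m_j. Candidate boundaries are the 255
# interior bin edges; the first maximizer (lexicographically smallest
# boundary tuple) is returned, making the choice deterministic.
.otsu_thresholds <- function(x, classes) {
  h <- .hist256(x)
  if (sum(h > 0) < classes)
    stop("degenerate-input error: fewer than ", classes,
         " distinct intensity levels")
  p <- h / sum(h)
  mids <- (seq_len(.NBINS) - 0.5) / .NBINS
  cw <- cumsum(p)                # cumulative weight up to bin i
  cm <- cumsum(p * mids)         # cumulative first moment
  csum <- function(i) if (i == 0L) 0 else cw[i]
  msum <- function(i) if (i == 0L) 0 else cm[i]
  if (classes == 2L) {
    w1 <- cw[-.NBINS]; m1 <- cm[-.NBINS]
    w2 <- 1 - w1; m2 <- cm[.NBINS] - m1
    sb <- ifelse(w1 > 0 & w2 > 0, m1^2 / w1 + m2^2 / w2, -Inf)
    k <- which.max(sb)
    return(k / .NBINS)
  }
  combos <- utils::combn(.NBINS - 1L, classes - 1L)
  best <- -Inf; best_cut <- NULL
  for (j in seq_len(ncol(combos))) {
    cuts <- c(0L, combos[, j], .NBINS)
    sb <- 0
    ok <- TRUE
    for (cl in seq_len(classes)) {
      w <- csum(cuts[cl + 1L]) - csum(cuts[cl])
      if (w <= 0) { ok <- FALSE; break }
      m <- msum(cuts[cl + 1L]) - msum(cuts[cl])
      sb <- sb + m^2 / w
    }
    if (ok && sb > best + 1e-15) { best <- sb; best_cut <- combos[, j] }
  }
  if (is.null(best_cut))
    stop("degenerate-input error: no valid multi-level threshold")
  best_cut / .NBINS
}

#' Otsu threshold of a slice
#'
#' Threshold maximizing the between-class variance of the 256-bin intensity
#' histogram.
#'
#' @param slice 2-D intensity matrix in `[0, 1]`.
#' @return Threshold on the `[0, 1]` scale.
#' @export
otsu_threshold <- function(slice) {
  if (max(slice) - min(slice) < 1 / .NBINS)
    stop("degenerate-input error: constant slice has no Otsu threshold")
  .otsu_thresholds(slice, 2L)
}

#' Binarize a slice
#'
#' `mask = slice >= threshold`. With `threshold = "auto"` the Otsu threshold
#' of the slice is used.
#'
#' @param slice 2-D intensity matrix in `[0, 1]`.
#' @param threshold numeric threshold or `"auto"` (default).
#' @return Logical mask matrix.
#' @export
#' @examples
#' binarize(matrix(c(0.2, 0.9, 0.2, 0.9), 2), threshold = 0.5)
binarize <- function(slice, threshold = "auto") {
  if (min(slice) < 0 || max(slice) > 1)
    stop("validation error: slice intensities outside [0, 1]")
  thr <- if (identical(threshold, "auto")) otsu_threshold(slice)
         else as.numeric(threshold)
  slice >= thr
}

#' Label connected components
#'
#' Two-pass labelling of the foreground of a binary mask. Two pixels share a
#' label iff they are connected under the chosen connectivity; labels are
#' numbered 1, 2, ... in raster-scan (row-major) order of the first pixel of
#' each component. Per-label pixel areas and priority weights (dense rank by
#' area, 1 = biggest, ties by smaller label) are attached.
#'
#' @param mask logical (or 0/1) matrix.
#' @param connectivity 4 or 8 (default 8, the neighbourhood scanned when
#'   growing tumour blobs).
#' @return An object of class `labeling`: list with `labels` (integer matrix,
#'   0 = background), `areas` (named integer vector), `weights` (named integer
#'   vector), `connectivity`.
#' @export
#' @examples
#' m <- matrix(FALSE, 3, 3); m[1, 1] <- m[2, 2] <- TRUE
#' label_components(m, connectivity = 8)$areas  # one blob
#' label_components(m, connectivity = 4)$areas  # two blobs
label_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8))
    stop("parameter error: connectivity must be 4 or 8")
  mask <- .as_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nxt <- 0L
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      if (!mask[r, cc]) next
      nb <- integer(0)
      if (cc > 1L && labels[r, cc - 1L] > 0L) nb <- c(nb, labels[r, cc - 1L])
      if (r > 1L) {
        if (labels[r - 1L, cc] > 0L) nb <- c(nb, labels[r - 1L, cc])
        if (connectivity == 8) {
          if (cc > 1L && labels[r - 1L, cc - 1L] > 0L)
            nb <- c(nb, labels[r - 1L, cc - 1L])
          if (cc < nc && labels[r - 1L, cc + 1L] > 0L)
            nb <- c(nb, labels[r - 1L, cc + 1L])
        }
      }
      if (length(nb) == 0L) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        labels[r, cc] <- nxt
      } else {
        roots <- unique(vapply(nb, find, integer(1)))
        m <- min(roots)
        labels[r, cc] <- m
        for (rt in roots) parent[rt] <- m
      }
    }
  }
  if (nxt > 0L) {
    root_of <- vapply(seq_len(nxt), find, integer(1))
    labels[labels > 0L] <- root_of[labels[labels > 0L]]
    # renumber roots by raster order of first encounter
    raster <- as.vector(t(labels))
    firsts <- unique(raster[raster > 0L])
    remap <- integer(nxt)
    remap[firsts] <- seq_along(firsts)
    labels[labels > 0L] <- remap[labels[labels > 0L]]
  }
  k <- max(labels)
  areas <- if (k > 0L) tabulate(labels[labels > 0L], nbins = k) else integer(0)
  names(areas) <- if (k > 0L) seq_len(k) else character(0)
  weights <- integer(k)
  if (k > 0L) {
    ord <- order(-areas, seq_len(k))   # biggest first, ties by smaller label
    weights[ord] <- seq_len(k)
    names(weights) <- seq_len(k)
  }
  structure(list(labels = labels, areas = areas, weights = weights,
                 connectivity = connectivity),
            class = "labeling")
}

#' @export
print.labeling <- function(x, ...) {
  cat(sprintf("<labeling> %d component(s), %d foreground pixel(s), %d-connectivity\n",
              length(x$areas), sum(x$areas), x$connectivity))
  if (length(x$areas)) {
    show <- utils::head(order(x$weights), 5L)
    cat("  biggest areas:", paste0(names(x$areas)[show], ":", x$areas[show],
                                   collapse = " "), "\n")
  }
  invisible(x)
}

#' Select the biggest blob
#'
#' Returns the mask of the connected component with maximal pixel area (the
#' tumour-region candidate); ties are broken by the smallest label, i.e. the
#' component first encountered in raster order.
#'
#' @param labeling a [label_components()] result.
#' @return Logical mask of the biggest component.
#' @export
biggest_blob <- function(labeling) {
  if (!inherits(labeling, "labeling"))
    stop("validation error: 'labeling' must come from label_components()")
  if (length(labeling$areas) == 0L)
    stop("empty-selection error: no connected components")
  lab <- which.max(labeling$areas)  # first max = smallest label
  labeling$labels == lab
}

.as_mask <- function(mask) {
  if (is.matrix(mask) && is.logical(mask)) return(mask)
  if (is.matrix(mask) && all(mask %in% c(0, 1))) return(mask > 0)
  stop("validation error: mask must be a logical or 0/1 matrix")
}
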