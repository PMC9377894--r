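#' Greyscale MRI volume
#'
#' Container for an ordered stack of co-registered 2-D greyscale slices with
#' intensities in `[0, 1]`. Slices are indexed in the source numbering of the
#' acquisition: `slice_offset` records the source index of the first stored
#' slice, so a volume cropped to the tumour-visible slices 65--74 of a
#' 155-slice acquisition keeps its original slice numbers.
#'
#' @param data numeric array, either `slices x rows x cols` or a single
#'   2-D slice (promoted to a 1-slice volume). All values must lie in
#'   `[0, 1]` unless `normalize = TRUE`.
#' @param slice_offset integer, source index of the first slice (default 0).
#' @param source_path provenance string (file or directory of origin).
#' @param normalize if `TRUE`, min-max rescale `data` to `[0, 1]` first
#'   (a constant array maps to all zeros).
#'
#' @return An object of class `grey_volume`: a list with elements `data`
#'   (3-D array), `slice_offset` and `source_path`.
#' @seealso [normalize_intensity()], [load_volume()], [get_slice()]
#' @export
#' @examples
#' v <- grey_volume(array(runif(4 * 8 * 8), c(4, 8, 8)), slice_offset = 65)
#' n_slices(v)
#' dim(get_slice(v, 66))
grey_volume <- function(data, slice_offset = 0L, source_path = NA_character_,
                        normalize = FALSE) {
  if (is.matrix(data)) {
    data <- array(data, c(1L, nrow(data), ncol(data)))
  }
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("validation error: volume data must be a slices x rows x cols array")
  if (dim(data)[1] < 1L)
    stop("validation error: volume must contain at least one slice")
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data)))
    stop("validation error: volume contains NaN or infinite intensities")
  if (normalize) {
    data <- .minmax01(data)
  } else if (min(data) < 0 || max(data) > 1) {
    stop("validation error: intensities outside [0, 1]; use normalize = TRUE")
  }
  structure(
    list(data = data, slice_offset = as.integer(slice_offset),
         source_path = source_path),
    class = "grey_volume"
  )
}

#' Binary mask volume
#'
#' A stack of binary (0/1) slice masks paired with a [grey_volume()] of the
#' same shape, e.g. a ground-truth tumour label volume.
#'
#' @param data array of 0/1 (or logical) values, `slices x rows x cols`,
#'   or a single 2-D mask.
#' @param slice_offset integer, source index of the first slice.
#' @param paired_dim optional shape of the paired grey volume; a mismatch is
#'   a validation error.
#' @return An object of class `mask_volume` with integer 0/1 `data`.
#' @export
mask_volume <- function(data, slice_offset = 0L, paired_dim = NULL) {
  if (is.matrix(data)) data <- array(data, c(1L, nrow(data), ncol(data)))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("validation error: mask data must be a slices x rows x cols array")
  if (is.logical(data)) {
    data <- array(as.integer(data), dim(data))
  }
  if (anyNA(data) || !all(data %in% c(0, 1)))
    stop("validation error: mask values must be 0 or 1")
  if (!is.null(paired_dim) && !identical(as.integer(dim(data)),
                                         as.integer(paired_dim)))
    stop("validation error: mask shape does not match its paired volume")
  structure(
    list(data = array(as.integer(data), dim(data)),
         slice_offset = as.integer(slice_offset)),
    class = "mask_volume"
  )
}

#' Min-max normalize raw intensities into a grey volume
#'
#' Rescales an arbitrary finite numeric array linearly so its minimum maps to
#' 0 and its maximum to 1; a constant array maps to all zeros.
#'
#' @param raw numeric array (2-D or 3-D) of finite intensities.
#' @param slice_offset,source_path passed to [grey_volume()].
#' @return A [grey_volume()].
#' @export
#' @examples
#' v <- normalize_intensity(array(0:255, c(1, 16, 16)))
#' range(v$data)
normalize_intensity <- function(raw, slice_offset = 0L,
                                source_path = NA_character_) {
  if (anyNA(raw) || any(!is.finite(raw)))
    stop("validation error: input contains NaN or infinite values")
  grey_volume(.minmax01(raw), slice_offset = slice_offset,
              source_path = source_path)
}

.minmax01 <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi > lo) (x - lo) / (hi - lo) else array(0, dim(x))
}

#' Number of slices in a volume
#' @param volume a [grey_volume()] or [mask_volume()].
#' @return integer slice count.
#' @export
n_slices <- function(volume) dim(volume$data)[1]

#' Extract one slice by source number
#'
#' @param volume a [grey_volume()] or [mask_volume()].
#' @param number slice index in source numbering (i.e. honouring
#'   `slice_offset`).
#' @return The slice as a `rows x cols` matrix.
#' @export
get_slice <- function(volume, number) {
  i <- as.integer(number) - volume$slice_offset + 1L
  if (i < 1L || i > n_slices(volume))
    stop("parameter error: slice ", number, " outside volume range ",
         volume$slice_offset, ":", volume$slice_offset + n_slices(volume) - 1L)
  volume$data[i, , ]
}

#' @export
print.grey_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<grey_volume> %d slice(s) of %d x %d, slices %d:%d\n",
              d[1], d[2], d[3], x$slice_offset, x$slice_offset + d[1] - 1L))
  cat(sprintf("  intensity range [%.3f, %.3f]", min(x$data), max(x$data)))
  if (!is.na(x$source_path)) cat("  source:", x$source_path)
  cat("\n")
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mask_volume> %d slice(s) of %d x %d, %d foreground pixel(s)\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}
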