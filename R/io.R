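#' Load a greyscale volume from disk
#'
#' Reads a NIfTI volume (BraTS-style, one file per sequence) or a directory of
#' 2-D greyscale PNG/TIFF images (sorted by file name, one slice each), then
#' min-max normalizes intensities to `[0, 1]`.
#'
#' The last NIfTI axis is taken as the slice axis (BraTS convention); rows and
#' columns follow array order, with 0-based slice numbering offset by
#' `slice_offset`.
#'
#' @param path path to a `.nii`/`.nii.gz` file or to a directory of
#'   PNG/TIFF slices.
#' @param format one of `"auto"`, `"nifti"`, `"image_stack"`.
#' @param slice_offset source index of the first slice (default 0); use 65 to
#'   address a cropped stack by its original slice numbers.
#' @return A [grey_volume()].
#' @export
load_volume <- function(path, format = c("auto", "nifti", "image_stack"),
                        slice_offset = 0L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "image_stack" else "nifti"
  }
  if (format == "nifti") {
    raw <- .read_nifti_array(path)
  } else {
    raw <- .read_image_stack(path)
  }
  if (length(raw) == 0L || dim(raw)[1] < 1L)
    stop("validation error: empty volume at ", path)
  normalize_intensity(raw, slice_offset = slice_offset, source_path = path)
}

.read_nifti_array <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop("format error: cannot read NIfTI file ", path,
                         " (", conditionMessage(e), ")"))
  a <- as.array(img)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  if (length(dim(a)) != 3L)
    stop("format error: expected a 3-D volume, got ",
         length(dim(a)), "-D data in ", path)
  aperm(a, c(3L, 1L, 2L))  # (x, y, z) -> (slice, row, col)
}

.read_image_stack <- function(path) {
  if (!dir.exists(path)) stop("format error: directory not found: ", path)
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L)
    stop("format error: no PNG/TIFF slices in ", path)
  slices <- lapply(files, .read_grey_image)
  shp <- dim(slices[[1]])
  if (!all(vapply(slices, function(s) identical(dim(s), shp), logical(1))))
    stop("validation error: slices in ", path, " have differing shapes")
  out <- array(0, c(length(slices), shp))
  for (i in seq_along(slices)) out[i, , ] <- slices[[i]]
  out
}

.read_grey_image <- function(file) {
  img <- tryCatch({
    if (grepl("\\.png$", file, ignore.case = TRUE)) png::readPNG(file)
    else tiff::readTIFF(file)
  }, error = function(e)
    stop("format error: cannot read image ", file,
         " (", conditionMessage(e), ")"))
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
  img
}

#' Save / load a binary mask volume as NIfTI
#'
#' Masks are written as 8-bit label volumes; a save/load round trip is
#' bit-exact.
#'
#' @param mask a [mask_volume()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `save_mask()` returns `path` invisibly; `load_mask()` returns a
#'   [mask_volume()].
#' @export
save_mask <- function(mask, path) {
  if (!inherits(mask, "mask_volume"))
    stop("validation error: 'mask' must be a mask_volume")
  a <- aperm(mask$data, c(2L, 3L, 1L))  # (slice,row,col) -> (x,y,z)
  storage.mode(a) <- "integer"
  .write_nifti(a, path, "uint8")
  invisible(path)
}

#' @rdname save_mask
#' @param slice_offset source index of the first slice for the loaded mask.
#' @export
load_mask <- function(path, slice_offset = 0L) {
  a <- .read_nifti_array(path)
  mask_volume(a != 0, slice_offset = slice_offset)
}

#' Save a greyscale volume as 16-bit NIfTI
#'
#' Intensities in `[0, 1]` are quantized to 16 bits; a round trip through
#' [load_volume()] reproduces the data within 1/65535.
#'
#' @param volume a [grey_volume()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path) {
  if (!inherits(volume, "grey_volume"))
    stop("validation error: 'volume' must be a grey_volume")
  a <- aperm(round(volume$data * 65535), c(2L, 3L, 1L))
  storage.mode(a) <- "integer"
  .write_nifti(a, path, "uint16")
  invisible(path)
}

.write_nifti <- function(a, path, datatype) {
  ok <- tryCatch({
    RNifti::writeNifti(RNifti::asNifti(a, datatype = datatype), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path))
    stop("I/O error: cannot write ", path)
  invisible(path)
}

#' Write an RGB overlay or greyscale slice to PNG
#'
#' @param image a `rows x cols` greyscale matrix in `[0,1]` or a
#'   `rows x cols x 3` RGB array in `[0,1]`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
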