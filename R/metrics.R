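# Segmentation evaluation: Dice overlap index (DOI), Jaccard index (JI),
# mean squared error and peak signal-to-noise ratio.

.check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("validation error: shapes differ")
}

#' Dice overlap index
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param pred,truth binary (logical or 0/1) arrays of identical shape.
#' @return Value in `[0, 1]`.
#' @export
#' @examples
#' a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
#' dice(a, a)
dice <- function(pred, truth) {
  .check_same_shape(pred, truth)
  pred <- pred > 0; truth <- truth > 0
  denom <- sum(pred) + sum(truth)
  if (denom == 0) return(1)
  2 * sum(pred & truth) / denom
}

#' Jaccard index
#'
#' `|A n B| / |A u B|`; 1 when both masks are empty. Related to Dice by
#' `D = 2J / (1 + J)`.
#'
#' @inheritParams dice
#' @return Value in `[0, 1]`.
#' @export
jaccard <- function(pred, truth) {
  .check_same_shape(pred, truth)
  pred <- pred > 0; truth <- truth > 0
  u <- sum(pred | truth)
  if (u == 0) return(1)
  sum(pred & truth) / u
}

#' Mean squared error
#'
#' Mean of squared pixel differences between two `[0, 1]`-scaled images.
#'
#' @param pred,truth numeric arrays of identical shape.
#' @return Non-negative value.
#' @export
mse <- function(pred, truth) {
  .check_same_shape(pred, truth)
  mean((as.numeric(pred) - as.numeric(truth))^2)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` in dB; `Inf` when the images are identical.
#'
#' @inheritParams mse
#' @param peak signal peak (1 for normalized images, 255 for 8-bit).
#' @return Value in dB (`Inf` sentinel at zero error).
#' @export
psnr <- function(pred, truth, peak = 1.0) {
  m <- mse(pred, truth)
  if (m == 0) return(Inf)
  10 * log10(peak^2 / m)
}

#' Full evaluation report
#'
#' Computes the four evaluation measures between a predicted mask and a
#' ground-truth mask (masks are treated as 0/1 intensity images for MSE and
#' PSNR).
#'
#' @param pred,truth binary arrays of identical shape.
#' @param peak PSNR peak (default 1).
#' @param name optional label for the report row.
#' @return Object of class `eval_report`: list with `doi`, `ji`, `mse`,
#'   `psnr`, `name`.
#' @export
eval_report <- function(pred, truth, peak = 1.0, name = NA_character_) {
  p <- if (is.list(pred) && !is.null(pred$data)) pred$data else pred
  t <- if (is.list(truth) && !is.null(truth$data)) truth$data else truth
  structure(list(name = name,
                 doi = dice(p, t),
                 ji = jaccard(p, t),
                 mse = mse(p > 0, t > 0),
                 psnr = psnr(p > 0, t > 0, peak)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Segmentation evaluation",
      if (!is.na(x$name)) paste0("(", x$name, ")"), "\n")
  cat(sprintf("  DOI  %.4f\n  JI   %.4f\n  MSE  %.4g\n  PSNR %s dB\n",
              x$doi, x$ji, x$mse,
              if (is.infinite(x$psnr)) "Inf" else sprintf("%.2f", x$psnr)))
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  data.frame(name = x$name, doi = x$doi, ji = x$ji, mse = x$mse,
             psnr = x$psnr, stringsAsFactors = FALSE)
}
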