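# Brute-force oracles, independent of the package internals.

# Flood-fill connected-component labelling from every unvisited foreground
# pixel; labels numbered in raster (row-major) order of first encounter.
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    moves <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    moves <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  lab <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (!mask[r, cc] || labels[r, cc] > 0L) next
    lab <- lab + 1L
    stack <- matrix(c(r, cc), 1)
    labels[r, cc] <- lab
    while (nrow(stack) > 0) {
      p <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      for (m in seq_len(nrow(moves))) {
        rr <- p[1] + moves[m, 1]; ccc <- p[2] + moves[m, 2]
        if (rr >= 1 && rr <= nr && ccc >= 1 && ccc <= nc &&
            mask[rr, ccc] && labels[rr, ccc] == 0L) {
          labels[rr, ccc] <- lab
          stack <- rbind(stack, c(rr, ccc))
        }
      }
    }
  }
  labels
}

# Are two labelings identical up to a label permutation?
same_partition <- function(a, b) {
  if (!identical(a > 0, b > 0)) return(FALSE)
  fa <- a[a > 0]; fb <- b[b > 0]
  length(unique(fa)) == length(unique(fb)) &&
    !anyDuplicated(unique(cbind(fa, fb)))
}

# Coordinate-scan bounding box.
oracle_bbox <- function(mask) {
  rmin <- Inf; rmax <- -Inf; cmin <- Inf; cmax <- -Inf
  for (r in seq_len(nrow(mask))) for (cc in seq_len(ncol(mask))) {
    if (mask[r, cc]) {
      rmin <- min(rmin, r); rmax <- max(rmax, r)
      cmin <- min(cmin, cc); cmax <- max(cmax, cc)
    }
  }
  c(rmin, rmax, cmin, cmax)
}

# Index-range accumulation quadrant means (split at floor(n/2), extra
# row/col bottom/right).
oracle_quadrant_means <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  hr <- nr %/% 2; hc <- nc %/% 2
  acc <- numeric(4); cnt <- numeric(4)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    q <- if (r <= hr && cc <= hc) 1 else if (r <= hr) 2
         else if (cc <= hc) 3 else 4
    acc[q] <- acc[q] + img[r, cc]; cnt[q] <- cnt[q] + 1
  }
  acc / cnt
}

# Pairwise sign-change contour scan: phi < 0 pixels with a non-negative
# 4-neighbour.
oracle_contour <- function(phi) {
  nr <- nrow(phi); nc <- ncol(phi)
  out <- NULL
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (phi[r, cc] >= 0) next
    nb <- rbind(c(r - 1, cc), c(r + 1, cc), c(r, cc - 1), c(r, cc + 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nr & nb[, 2] >= 1 & nb[, 2] <= nc, ,
             drop = FALSE]
    if (any(phi[nb] >= 0)) out <- rbind(out, c(r, cc))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

random_mask <- function(nr = 16, nc = 16, p = 0.4) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

# Noise-free bright disc on dark ground plus its truth mask.
disc_image <- function(nr = 100, nc = 100, centre = c(50, 50), radius = 18,
                       fg = 0.85, bg = 0.05) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d <- sqrt((rows - centre[1])^2 + (cols - centre[2])^2)
  img <- matrix(bg, nr, nc)
  img[d <= radius] <- fg
  list(image = img, truth = d <= radius)
}
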