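# Independent brute-force oracles used to validate the fast implementations.

# O(n w^2) sliding-window mean with replicate padding.
brute_local_mean <- function(img, w) {
  h <- (w - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rows <- pmin(pmax(seq(i - h, i + h), 1), nr)
    cols <- pmin(pmax(seq(j - h, j + h), 1), nc)
    out[i, j] <- mean(img[rows, cols])
  }
  out
}

# Stack-based flood-fill connected-component labeler (4- or 8-connectivity),
# labels in raster-scan order of first pixel.
flood_fill_label <- function(binary, connectivity = 8) {
  nr <- nrow(binary); nc <- ncol(binary)
  lab <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    as.matrix(expand.grid(dr = -1:1, dc = -1:1)[-5, ])
  }
  next_lab <- 0L
  for (i0 in seq_len(nr)) for (j0 in seq_len(nc)) {
    if (binary[i0, j0] && lab[i0, j0] == 0L) {
      next_lab <- next_lab + 1L
      stack <- list(c(i0, j0)); lab[i0, j0] <- next_lab
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (k in seq_len(nrow(nbr))) {
          r <- p[1] + nbr[k, 1]; cc <- p[2] + nbr[k, 2]
          if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
              binary[r, cc] && lab[r, cc] == 0L) {
            lab[r, cc] <- next_lab
            stack[[length(stack) + 1]] <- c(r, cc)
          }
        }
      }
    }
  }
  lab
}

# Exhaustive Otsu: histogram the sample exactly as the implementation
# specifies (equal-width bins, midpoints as class values) and scan every
# interior bin edge for the minimum pooled within-class variance.
brute_otsu <- function(values, bins = 256) {
  rng <- range(values)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  bin <- pmin(pmax(findInterval(values, breaks, rightmost.closed = TRUE), 1),
              bins)
  counts <- tabulate(bin, nbins = bins)
  mids <- (breaks[-1] + breaks[-(bins + 1)]) / 2
  best_edge <- NA_real_; best_wcv <- Inf
  for (k in seq_len(bins - 1)) {
    n0 <- sum(counts[1:k]); n1 <- sum(counts[(k + 1):bins])
    if (n0 == 0 || n1 == 0) next
    m0 <- sum(counts[1:k] * mids[1:k]) / n0
    m1 <- sum(counts[(k + 1):bins] * mids[(k + 1):bins]) / n1
    v0 <- sum(counts[1:k] * (mids[1:k] - m0)^2)
    v1 <- sum(counts[(k + 1):bins] * (mids[(k + 1):bins] - m1)^2)
    wcv <- (v0 + v1) / (n0 + n1)
    if (wcv < best_wcv - 1e-12) { best_wcv <- wcv; best_edge <- breaks[k + 1] }
  }
  best_edge
}

# Partition equality of two labelings (same components regardless of ids).
same_partition <- function(a, b) {
  fa <- a[a > 0 | b > 0]; fb <- b[a > 0 | b > 0]
  if (any((fa == 0) != (fb == 0))) return(FALSE)
  length(unique(paste(fa, fb))) == length(unique(fa)) &&
    length(unique(paste(fa, fb))) == length(unique(fb))
}

# Minimal image_set around given rasters, defaulting the other channels.
tiny_set <- function(bf = NULL, live = NULL, dead = NULL, nr = 16, nc = 16,
                     pixel_area = 38.62, group = "treatment", well = "w1") {
  z <- matrix(0, nr, nc)
  image_set(bf %||% z + 100, live %||% z, dead %||% z,
            pixel_area = pixel_area, well_id = well, group = group)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# One label map from a logical mask, labeling with the package's own
# machinery disabled (direct construction) so quantification tests do not
# depend on segmentation.
mask_label_map <- function(mask, pixel_area = 38.62) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- 1L
  label_map(lab, pixel_area)
}
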