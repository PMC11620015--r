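# Small raster helpers shared across the pipeline.

# Gaussian blur of a plain matrix; EBImage works in [0,1]-ish intensities
# but is linear, so we pass values through unscaled.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  out <- EBImage::gblur(x, sigma = sigma)
  matrix(as.numeric(out), nrow = nrow(x))
}

# Binary dilation with a Euclidean disc of radius r pixels (r = 1 is the
# 4-neighbourhood plus centre). Implemented by shifting, which keeps the
# structuring element exactly a disc of pixel-centre distances <= r.
dilate_disc <- function(x, r) {
  if (r <= 0) return(x)
  out <- x
  ri <- floor(r)
  for (di in -ri:ri) for (dj in -ri:ri) {
    if ((di == 0 && dj == 0) || di * di + dj * dj > r * r) next
    out <- out | shift_logical(x, di, dj)
  }
  out
}

# Shift a logical matrix by (di, dj) pixels, filling with FALSE.
shift_logical <- function(x, di, dj) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(FALSE, h, w)
  rs <- max(1, 1 + di):min(h, h + di)
  cs <- max(1, 1 + dj):min(w, w + dj)
  if (length(rs) && length(cs)) out[rs, cs] <- x[rs - di, cs - dj]
  out
}

#' Label 8-connected components of a binary raster
#'
#' Flow-deficit components are defined with 8-connectivity (diagonally
#' touching deficit pixels belong to one deficit). Labels are positive
#' integers, background is 0. Implemented as vectorised min-label
#' propagation, which converges in at most the maximal within-component
#' path length.
#'
#' @param x Logical matrix.
#' @return Integer matrix of component labels (0 = background), with the
#'   number of components as attribute `n`.
#' @export
label_components_8 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  lab <- matrix(0L, h, w)
  lab[x] <- which(x)  # seed with linear pixel index
  offsets <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                   c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  repeat {
    new <- lab
    for (k in seq_len(nrow(offsets))) {
      sh <- shift_int(lab, offsets[k, 1L], offsets[k, 2L])
      upd <- x & sh > 0L & (new == 0L | sh < new)
      new[upd] <- sh[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  # renumber to consecutive 1..n
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids)) {
    lab[lab > 0L] <- match(lab[lab > 0L], ids)
  }
  attr(lab, "n") <- length(ids)
  lab
}

shift_int <- function(x, di, dj) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0L, h, w)
  rs <- max(1, 1 + di):min(h, h + di)
  cs <- max(1, 1 + dj):min(w, w + dj)
  if (length(rs) && length(cs)) out[rs, cs] <- x[rs - di, cs - dj]
  out
}

# Otsu threshold (between-class variance maximiser) on a 256-bin histogram
# of the supplied values. Returns NA for (near-)constant input.
otsu_threshold <- function(vals, n_bins = 256L) {
  rng <- range(vals)
  if (diff(rng) <= 0) return(NA_real_)
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  counts <- tabulate(.bincode(vals, breaks, include.lowest = TRUE), n_bins)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w <- counts / sum(counts)
  cw <- cumsum(w)
  cmu <- cumsum(w * mids)
  mu <- cmu[n_bins]
  # between-class variance for threshold after bin k
  valid <- cw > 0 & cw < 1
  bcv <- rep(-Inf, n_bins)
  bcv[valid] <- (mu * cw[valid] - cmu[valid])^2 / (cw[valid] * (1 - cw[valid]))
  k <- which.max(bcv)
  breaks[k + 1L]
}
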