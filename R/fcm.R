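#' Fuzzy C-means global threshold
#'
#' Two-cluster fuzzy C-means (fuzzifier m = 2) on the intensity
#' distribution of the unmasked pixels, accelerated on a 256-bin
#' histogram. Cluster centers are initialised at the 10th and 90th
#' percentiles of the unmasked intensities and iterated until the largest
#' center change falls below `tol` (default 1e-6) or `max_iter` (default
#' 300) iterations. The global threshold is the midpoint of the converged
#' centers. The procedure is fully deterministic.
#'
#' @param img An [enface_image()] (typically the compensated CC flow).
#' @param exclude Optional exclusion [binary_mask()].
#' @param tol Convergence tolerance on the center change.
#' @param max_iter Maximum number of iterations.
#' @param n_bins Number of histogram bins (default 256).
#' @return An object of class `threshold_result` with fields `threshold`,
#'   `cluster_centers` (low, high), `iterations`, `converged`.
#' @export
fcm_threshold <- function(img, exclude = NULL, tol = 1e-6, max_iter = 300L,
                          n_bins = 256L) {
  px <- if (inherits(img, "enface_image")) img$pixels else as.matrix(img)
  keep <- if (is.null(exclude)) rep(TRUE, length(px)) else !exclude$pixels
  vals <- as.numeric(px[keep])
  if (length(unique(vals)) < 2L) {
    stop("degenerate intensity distribution (fewer than 2 distinct values)",
         call. = FALSE)
  }
  rng <- range(vals)
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  counts <- tabulate(.bincode(vals, breaks, include.lowest = TRUE), n_bins)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  nz <- counts > 0L
  res <- fcm_1d(mids[nz], counts[nz],
                centers = stats::quantile(vals, c(0.1, 0.9), names = FALSE),
                tol = tol, max_iter = max_iter)
  structure(list(threshold = mean(res$centers),
                 cluster_centers = sort(res$centers),
                 iterations = res$iterations,
                 converged = res$converged),
            class = "threshold_result")
}

# Weighted 1D fuzzy C-means with m = 2 on values x with counts w.
fcm_1d <- function(x, w, centers, tol = 1e-6, max_iter = 300L) {
  c1 <- centers[1L]; c2 <- centers[2L]
  if (c1 == c2) c2 <- c1 + diff(range(x)) * 0.1 + .Machine$double.eps
  it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    d1 <- (x - c1)^2
    d2 <- (x - c2)^2
    # membership u1 = 1 / (1 + d1/d2); handle exact hits
    u1 <- ifelse(d1 == 0, 1, ifelse(d2 == 0, 0, d2 / (d1 + d2)))
    u2 <- 1 - u1
    n1 <- sum(w * u1^2); n2 <- sum(w * u2^2)
    new1 <- if (n1 > 0) sum(w * u1^2 * x) / n1 else c1
    new2 <- if (n2 > 0) sum(w * u2^2 * x) / n2 else c2
    delta <- max(abs(new1 - c1), abs(new2 - c2))
    c1 <- new1; c2 <- new2
    if (delta < tol) { converged <- TRUE; break }
  }
  list(centers = c(c1, c2), iterations = it, converged = converged)
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> threshold %.4g (centers %.4g / %.4g), %d iter%s\n",
              x$threshold, x$cluster_centers[1L], x$cluster_centers[2L],
              x$iterations, if (x$converged) "" else " [not converged]"))
  invisible(x)
}
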