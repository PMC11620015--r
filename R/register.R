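#' Rigid transform between repeat scans
#'
#' Maps a moving scan into the fixed (baseline) frame: a pixel at
#' 0-based `(row, col)` in the moving image lands at
#' `(row + dy_px, col + dx_px)` after rotation by `theta_deg` about the
#' image centre.
#'
#' @param dx_px,dy_px Column / row translation in pixels.
#' @param theta_deg Rotation in degrees (counter-clockwise).
#' @param score Registration quality (normalised correlation at the
#'   optimum; 1 for identical images).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(dx_px = 0, dy_px = 0, theta_deg = 0, score = NA_real_) {
  structure(list(dx_px = as.numeric(dx_px), dy_px = as.numeric(dy_px),
                 theta_deg = as.numeric(theta_deg), score = as.numeric(score)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> dx %+g px, dy %+g px, theta %+g deg (score %.3f)\n",
              x$dx_px, x$dy_px, x$theta_deg, x$score))
  invisible(x)
}

#' Register one en-face image to a fixed baseline
#'
#' Repeat scans of the same eye are registered on their
#' retinal-vasculature en-face images, the first scan serving as the
#' baseline. Translation is estimated at integer-pixel resolution by an
#' FFT correlation-peak search; an optional rotation is found by
#' exhaustive search over `±rot_range_deg` in `rot_step_deg` steps
#' (default off, as same-day repeats are rotationally stable). The score
#' is the Pearson correlation of the overlapping region at the optimum.
#'
#' @param moving,fixed Retinal-vasculature [enface_image()]s of the same
#'   geometry.
#' @param rotation Search over rotations as well? (default `FALSE`).
#' @param rot_range_deg,rot_step_deg Rotation search range / step.
#' @param max_shift_px Largest |shift| considered (default a quarter of
#'   the image).
#' @param min_score Registrations scoring below this fail with an error
#'   (default 0.2).
#' @return A [rigid_transform()] mapping `moving` into the fixed frame.
#' @export
register_enface <- function(moving, fixed, rotation = FALSE,
                            rot_range_deg = 5, rot_step_deg = 0.25,
                            max_shift_px = NULL, min_score = 0.2) {
  check_geometry_match(moving$geometry, fixed$geometry, "moving and fixed")
  if (is.null(max_shift_px)) {
    max_shift_px <- floor(min(dim(fixed$pixels)) / 4)
  }
  thetas <- if (rotation) seq(-rot_range_deg, rot_range_deg, by = rot_step_deg) else 0
  best <- NULL
  for (th in thetas) {
    mv <- if (th == 0) moving$pixels else
      resample_rigid(moving$pixels, rigid_transform(0, 0, th), "bilinear")$pixels
    sh <- correlation_shift(mv, fixed$pixels, max_shift_px)
    cand <- rigid_transform(sh["dx"], sh["dy"], th, sh["score"])
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  if (!is.finite(best$score) || best$score < min_score) {
    stop(sprintf("registration failed: score %.3f below floor %.3f",
                 best$score, min_score), call. = FALSE)
  }
  best
}

# Integer-pixel translation by FFT cross-correlation of mean-subtracted
# images, scored by Pearson correlation on the overlap.
correlation_shift <- function(moving, fixed, max_shift) {
  h <- nrow(fixed); w <- ncol(fixed)
  f0 <- fixed - mean(fixed)
  m0 <- moving - mean(moving)
  cc <- Re(stats::fft(stats::fft(f0) * Conj(stats::fft(m0)), inverse = TRUE))
  # cc[dy+1, dx+1] (mod size) = correlation when moving is shifted by (dy, dx)
  dys <- c(0:(h - 1)); dys[dys > h / 2] <- dys[dys > h / 2] - h
  dxs <- c(0:(w - 1)); dxs[dxs > w / 2] <- dxs[dxs > w / 2] - w
  ok <- outer(abs(dys) <= max_shift, abs(dxs) <= max_shift)
  cc[!ok] <- -Inf
  peak <- which.max(cc)
  dy <- dys[(peak - 1L) %% h + 1L]
  dx <- dxs[(peak - 1L) %/% h + 1L]
  # score on the overlap
  rs_f <- max(1, 1 + dy):min(h, h + dy); cs_f <- max(1, 1 + dx):min(w, w + dx)
  a <- fixed[rs_f, cs_f]
  b <- moving[rs_f - dy, cs_f - dx]
  score <- if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else stats::cor(as.vector(a), as.vector(b))
  c(dx = dx, dy = dy, score = score)
}

# Rigid resampling shared by intensity (bilinear) and binary (nearest)
# rasters; returns the resampled raster plus a logical validity matrix.
resample_rigid <- function(px, t, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  h <- nrow(px); w <- ncol(px)
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  th <- t$theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  # target (fixed-frame) pixel centres, 0-based
  R <- matrix(0:(h - 1), h, w)
  C <- matrix(0:(w - 1), h, w, byrow = TRUE)
  # invert: source = R(-theta) * (target - centre - shift) + centre
  yr <- R - cy - t$dy_px
  xr <- C - cx - t$dx_px
  src_r <- ct * yr + st * xr + cy
  src_c <- -st * yr + ct * xr + cx
  if (interp == "nearest") {
    ri <- round(src_r); ci <- round(src_c)
    valid <- ri >= 0 & ri <= h - 1 & ci >= 0 & ci <= w - 1
    out <- array(vector(mode = typeof(px), 1L), dim = c(h, w))
    out[valid] <- px[cbind(ri[valid] + 1, ci[valid] + 1)]
    list(pixels = out, valid = valid)
  } else {
    r0 <- floor(src_r); c0 <- floor(src_c)
    fr <- src_r - r0; fc <- src_c - c0
    valid <- src_r >= 0 & src_r <= h - 1 & src_c >= 0 & src_c <= w - 1
    # clamped neighbours: exact at edges because the weight beyond is 0
    r0c <- pmin(pmax(r0, 0), h - 1); c0c <- pmin(pmax(c0, 0), w - 1)
    r1c <- pmin(r0c + 1, h - 1); c1c <- pmin(c0c + 1, w - 1)
    g <- function(rr, cc) {
      matrix(px[cbind(as.vector(rr) + 1, as.vector(cc) + 1)], h, w)
    }
    vals <- (1 - fr) * (1 - fc) * g(r0c, c0c) + (1 - fr) * fc * g(r0c, c1c) +
      fr * (1 - fc) * g(r1c, c0c) + fr * fc * g(r1c, c1c)
    out <- matrix(0, h, w)
    out[valid] <- vals[valid]
    list(pixels = out, valid = valid)
  }
}

#' Apply a rigid transform to an image, mask or deficit map
#'
#' Intensity rasters are resampled bilinearly, binary rasters (masks and
#' flow-deficit maps) with nearest-neighbour interpolation so that binary
#' values stay exact. A validity mask marks target pixels that mapped
#' from inside the source raster.
#'
#' @param x An [enface_image()], [binary_mask()] or [flow_deficit_map()].
#' @param t A [rigid_transform()].
#' @return A list with `result` (same type as `x`) and `validity` (a
#'   validity [binary_mask()], `TRUE` = mapped from inside the source).
#' @export
apply_transform <- function(x, t) {
  UseMethod("apply_transform")
}

#' @export
apply_transform.enface_image <- function(x, t) {
  rs <- resample_rigid(x$pixels, t, "bilinear")
  list(result = enface_image(pmax(rs$pixels, 0), x$geometry, channel = x$channel,
                             metadata = x$metadata),
       validity = binary_mask(rs$valid, x$geometry, kind = "validity"))
}

#' @export
apply_transform.binary_mask <- function(x, t) {
  rs <- resample_rigid(x$pixels, t, "nearest")
  list(result = binary_mask(rs$pixels, x$geometry, kind = x$kind, role = x$role),
       validity = binary_mask(rs$valid, x$geometry, kind = "validity"))
}

#' @export
apply_transform.flow_deficit_map <- function(x, t) {
  rs <- resample_rigid(x$pixels, t, "nearest")
  list(result = flow_deficit_map(rs$pixels, x$geometry,
                                 source_threshold = x$source_threshold,
                                 min_gld_um = x$min_gld_um),
       validity = binary_mask(rs$valid, x$geometry, kind = "validity"))
}
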