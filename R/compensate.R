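#' Compensate the flow image for OCT signal attenuation
#'
#' Retinal/RPE abnormalities such as drusen attenuate the OCT signal
#' reaching the choriocapillaris, darkening both the CC flow and CC
#' structure en-face images and inflating apparent flow deficits. Because
#' the attenuation is shared, the structure image can be used to undo it.
#'
#' Two modes are available. `"divide"` (default) divides the flow image
#' by the smoothed structure image floored at a low quantile, which
#' removes a shared multiplicative attenuation field exactly.
#' `"complement"` multiplies the flow image by the inverted (maximum
#' minus smoothed) structure image. Both results are rescaled so the
#' median over unmasked pixels matches the median of the input flow
#' image, keeping the global threshold scale comparable.
#'
#' @param flow,structure [enface_image()]s with identical geometry.
#' @param mode `"divide"` or `"complement"`.
#' @param sigma_px Gaussian smoothing sigma applied to the structure
#'   image before use, in pixels (default 2).
#' @param floor_quantile Quantile of the smoothed structure used as the
#'   division floor to avoid noise amplification (default 0.05).
#' @param exclude Optional exclusion [binary_mask()]; masked pixels are
#'   ignored by the floor and median statistics.
#' @return A compensated [enface_image()] (channel `cc_flow`).
#' @export
compensate_flow <- function(flow, structure, mode = c("divide", "complement"),
                            sigma_px = 2, floor_quantile = 0.05,
                            exclude = NULL) {
  mode <- match.arg(mode)
  check_geometry_match(flow$geometry, structure$geometry, "flow and structure")
  if (max(structure$pixels) <= 0) {
    stop("degenerate structure image (all zero)", call. = FALSE)
  }
  keep <- if (is.null(exclude)) {
    matrix(TRUE, nrow(flow$pixels), ncol(flow$pixels))
  } else {
    check_geometry_match(flow$geometry, exclude$geometry, "flow and mask")
    !exclude$pixels
  }
  s <- gaussian_blur(structure$pixels, sigma_px)
  comp <- if (mode == "divide") {
    floor_val <- stats::quantile(s[keep], floor_quantile, names = FALSE)
    if (floor_val <= 0) {
      pos <- s[keep][s[keep] > 0]
      if (!length(pos)) stop("degenerate structure image (all zero)", call. = FALSE)
      floor_val <- min(pos)
    }
    flow$pixels / pmax(s, floor_val)
  } else {
    flow$pixels * (max(s[keep]) - s)
  }
  med_in <- stats::median(flow$pixels[keep])
  med_out <- stats::median(comp[keep])
  if (med_out > 0) comp <- comp * (med_in / med_out)
  comp[comp < 0] <- 0
  enface_image(comp, flow$geometry, channel = "cc_flow",
               metadata = flow$metadata)
}
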