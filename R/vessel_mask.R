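#' Derive a retinal vessel projection mask
#'
#' Large retinal vessels cast projection artifacts onto the
#' choriocapillaris slab; the affected pixels are excluded from both the
#' flow-deficit count and the valid-area denominator. Bright vessels are
#' segmented on the retinal-vasculature en-face image with a global
#' between-class-variance (Otsu) threshold and the segmentation is
#' dilated by a small disc to cover artifact fringes.
#'
#' @param retina A [enface_image()] with channel `retinal_vasculature`.
#' @param dilate_px Dilation disc radius in pixels (default 1).
#' @param threshold `"auto"` (Otsu over unmasked pixels) or a numeric
#'   intensity threshold; pixels strictly above it are vessel.
#' @param exclude Optional exclusion [binary_mask()] ignored by the
#'   automatic threshold.
#' @return An exclusion [binary_mask()] of kind `vessel_projection`. A
#'   constant image yields an empty mask with a warning.
#' @export
derive_vessel_projection_mask <- function(retina, dilate_px = 1,
                                          threshold = "auto", exclude = NULL) {
  px <- retina$pixels
  keep <- if (is.null(exclude)) matrix(TRUE, nrow(px), ncol(px)) else !exclude$pixels
  if (identical(threshold, "auto")) {
    threshold <- otsu_threshold(px[keep])
    if (is.na(threshold)) {
      warning("constant retinal image: vessel mask is empty", call. = FALSE)
      return(empty_mask(retina$geometry, kind = "vessel_projection"))
    }
  }
  vessel <- px > threshold
  vessel <- dilate_disc(vessel, dilate_px)
  binary_mask(vessel, retina$geometry, kind = "vessel_projection")
}
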