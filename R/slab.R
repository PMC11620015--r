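#' Slab definition
#'
#' A depth interval below Bruch's membrane from which an en-face image is
#' projected. The choriocapillaris slab is a 16-um slab starting 4 um
#' under BM; the sub-RPE slab runs from 64 to 400 um below BM.
#'
#' @param offset_start_um Start of the slab below BM, in micrometres
#'   (positive down, >= 0).
#' @param thickness_um Slab thickness in micrometres (> 0).
#' @param projection Projection statistic over the slab: `"mean"`
#'   (default) or `"max"`.
#' @return An object of class `slab_definition`.
#' @export
slab_definition <- function(offset_start_um, thickness_um,
                            projection = c("mean", "max")) {
  projection <- match.arg(projection)
  stopifnot(offset_start_um >= 0, thickness_um > 0)
  structure(list(offset_start_um = as.numeric(offset_start_um),
                 thickness_um = as.numeric(thickness_um),
                 projection = projection),
            class = "slab_definition")
}

#' @rdname slab_definition
#' @export
cc_slab <- function(projection = "mean") {
  slab_definition(4, 16, projection)
}

#' @rdname slab_definition
#' @export
sub_rpe_slab <- function(projection = "mean") {
  slab_definition(64, 400 - 64, projection)
}

#' Project an en-face image from a volumetric scan
#'
#' For every (row, col), projects the voxels whose depth below the local
#' BM surface lies in `[offset_start, offset_start + thickness)` um,
#' converting depths to voxel indices via the volume's axial spacing.
#'
#' @param vol A [volume_scan()].
#' @param slab A [slab_definition()].
#' @param channel `"cc_flow"` (projects the flow volume) or
#'   `"cc_structure"` (structure volume); the resulting image carries the
#'   same channel tag, or `"sub_rpe"` when `slab` starts >= 64 um.
#' @return An [enface_image()].
#' @export
extract_slab <- function(vol, slab, channel = c("cc_flow", "cc_structure")) {
  channel <- match.arg(channel)
  voxels <- if (channel == "cc_flow") vol$flow_voxels else vol$structure_voxels
  d <- dim(voxels)
  ax <- vol$axial_spacing_um
  # 0-based depth indices relative to BM with voxel k at depth k*ax
  rel <- seq(ceiling(slab$offset_start_um / ax),
             ceiling((slab$offset_start_um + slab$thickness_um) / ax) - 1L)
  if (!length(rel)) stop("slab thinner than one voxel", call. = FALSE)
  max_idx <- vol$bm_surface_px + max(rel)
  if (any(max_idx > d[3L] - 1L)) {
    bad <- which(max_idx > d[3L] - 1L, arr.ind = TRUE)[1L, ]
    stop(sprintf("slab exceeds volume depth at pixel (row=%d, col=%d)",
                 bad[1L] - 1L, bad[2L] - 1L), call. = FALSE)
  }
  h <- d[1L]; w <- d[2L]
  base <- matrix(seq_len(h), h, w) + (matrix(seq_len(w), h, w, byrow = TRUE) - 1L) * h
  plane <- h * w
  acc <- NULL
  for (j in rel) {
    layer <- voxels[as.vector(base + (vol$bm_surface_px + j) * plane)]
    dim(layer) <- c(h, w)
    acc <- if (is.null(acc)) {
      if (slab$projection == "mean") layer else layer
    } else if (slab$projection == "mean") acc + layer else pmax(acc, layer)
  }
  if (slab$projection == "mean") acc <- acc / length(rel)
  out_channel <- if (slab$offset_start_um >= 64) "sub_rpe" else channel
  enface_image(acc, vol$geometry, channel = out_channel)
}
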