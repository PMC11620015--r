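#' Flow-deficit map
#'
#' Binary raster of choriocapillaris flow deficits (`TRUE` = deficit),
#' with the threshold that produced it and, after size filtering, the
#' minimum retained greatest linear dimension.
#'
#' @param pixels Logical matrix.
#' @param geometry A [scan_geometry()].
#' @param source_threshold The [fcm_threshold()] result used, or `NULL`.
#' @param min_gld_um Minimum greatest linear dimension retained (um);
#'   `NA` before filtering.
#' @return An object of class `flow_deficit_map`.
#' @export
flow_deficit_map <- function(pixels, geometry, source_threshold = NULL,
                             min_gld_um = NA_real_) {
  pixels <- as.matrix(pixels)
  stopifnot(is.logical(pixels))
  if (nrow(pixels) != geometry$height_px || ncol(pixels) != geometry$width_px) {
    stop("deficit raster dimensions do not match geometry", call. = FALSE)
  }
  structure(list(pixels = pixels, geometry = geometry,
                 source_threshold = source_threshold,
                 min_gld_um = min_gld_um),
            class = "flow_deficit_map")
}

#' @export
print.flow_deficit_map <- function(x, ...) {
  cat(sprintf("<flow_deficit_map> %d x %d px, %d deficit px (%.2f%%)%s\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              100 * mean(x$pixels),
              if (is.na(x$min_gld_um)) " [unfiltered]"
              else sprintf(", GLD >= %g um", x$min_gld_um)))
  invisible(x)
}

#' Binarize a flow image into an unfiltered deficit map
#'
#' A pixel is a flow deficit iff it is unmasked and its intensity is
#' strictly below the global threshold. Excluded pixels are never
#' deficits.
#'
#' @param flow An [enface_image()] (compensated CC flow).
#' @param thr A `threshold_result` from [fcm_threshold()], or a bare
#'   numeric threshold.
#' @param exclude Optional exclusion [binary_mask()].
#' @return An unfiltered [flow_deficit_map()].
#' @export
binarize_flow <- function(flow, thr, exclude = NULL) {
  tval <- if (inherits(thr, "threshold_result")) thr$threshold else as.numeric(thr)
  fd <- flow$pixels < tval
  if (!is.null(exclude)) {
    check_geometry_match(flow$geometry, exclude$geometry, "flow and mask")
    fd <- fd & !exclude$pixels
  }
  flow_deficit_map(fd, flow$geometry,
                   source_threshold = if (inherits(thr, "threshold_result")) thr else NULL)
}

#' Remove flow deficits below a minimum greatest linear dimension
#'
#' Speckle noise and physiological intercapillary voids produce spurious
#' small deficits; components whose greatest linear dimension (GLD) is
#' strictly below `min_gld_um` are removed. Components are 8-connected
#' and GLD is the maximum pairwise pixel-centre distance converted to um
#' plus one pixel spacing, so an isolated pixel at 12-um spacing has
#' GLD 12 um (removed at the default 24-um cutoff) and two adjacent
#' pixels have GLD 24 um (kept).
#'
#' @param fd A [flow_deficit_map()].
#' @param min_gld_um Minimum GLD retained, in micrometres (default 24).
#' @return A filtered [flow_deficit_map()]; idempotent, never adds
#'   deficits.
#' @export
filter_small_deficits <- function(fd, min_gld_um = 24) {
  spacing <- fd$geometry$pixel_spacing_um
  lab <- label_components_8(fd$pixels)
  n <- attr(lab, "n")
  out <- fd$pixels
  if (n > 0L) {
    idx <- which(lab > 0L)
    rows <- (idx - 1L) %% nrow(lab)
    cols <- (idx - 1L) %/% nrow(lab)
    by_comp <- split(seq_along(idx), lab[idx])
    # quick keep: component whose bbox extent already guarantees the cutoff
    drop_comp <- logical(length(by_comp))
    for (k in seq_along(by_comp)) {
      sel <- by_comp[[k]]
      r <- rows[sel]; cc <- cols[sel]
      ext <- max(max(r) - min(r), max(cc) - min(cc))
      if ((ext + 1) * spacing >= min_gld_um) next  # GLD >= extent-based bound
      gld <- if (length(sel) == 1L) spacing else
        max(stats::dist(cbind(r, cc))) * spacing + spacing
      drop_comp[k] <- gld < min_gld_um
    }
    if (any(drop_comp)) {
      drop_labels <- as.integer(names(by_comp))[drop_comp]
      out[lab %in% drop_labels] <- FALSE
    }
  }
  flow_deficit_map(out, fd$geometry, source_threshold = fd$source_threshold,
                   min_gld_um = min_gld_um)
}

#' Quantify one scan: masks, compensation, threshold, size filter
#'
#' Runs the per-scan CCFD pipeline in its fixed order: merge the supplied
#' exclusion masks, compensate the flow image with the structure image
#' (unless disabled), add the retinal vessel-projection mask, threshold
#' the compensated flow with fuzzy C-means over the unmasked pixels,
#' binarize, and remove deficits smaller than the GLD cutoff.
#'
#' @param flow,structure CC flow and structure [enface_image()]s.
#' @param retina Optional retinal-vasculature [enface_image()] from which
#'   the vessel-projection mask is derived; a pre-computed mask can be
#'   supplied via `cfg$vessel$mask` instead.
#' @param masks List of exclusion [binary_mask()]s (HRF, CaD, hyperTDs, ...).
#' @param cfg A [quantify_config()].
#' @return A list with `fd_map` (filtered [flow_deficit_map()]),
#'   `combined_mask` (the exclusion mask actually applied, including
#'   vessel projections), `threshold` and `compensated` flow image.
#' @export
quantify_scan <- function(flow, structure = NULL, retina = NULL,
                          masks = list(), cfg = quantify_config()) {
  geom <- flow$geometry
  combined <- if (length(masks)) merge_masks(masks) else empty_mask(geom)
  comp <- flow
  if (cfg$compensation$mode != "off") {
    if (is.null(structure)) stop("compensation requires a structure image", call. = FALSE)
    comp <- withCallingHandlers(
      compensate_flow(flow, structure,
                      mode = cfg$compensation$mode,
                      sigma_px = cfg$compensation$sigma_px,
                      floor_quantile = cfg$compensation$floor_quantile,
                      exclude = combined),
      error = function(e) stop(sprintf("[compensate] %s", conditionMessage(e)),
                               call. = FALSE))
  }
  vmask <- cfg$vessel$mask
  if (is.null(vmask) && !is.null(retina)) {
    vmask <- derive_vessel_projection_mask(retina,
                                           dilate_px = cfg$vessel$dilate_px,
                                           threshold = cfg$vessel$threshold,
                                           exclude = combined)
  }
  if (!is.null(vmask)) combined <- merge_masks(list(combined, vmask))
  thr <- withCallingHandlers(
    fcm_threshold(comp, exclude = combined,
                  tol = cfg$fcm$tol, max_iter = cfg$fcm$max_iter),
    error = function(e) stop(sprintf("[threshold] %s", conditionMessage(e)),
                             call. = FALSE))
  fd <- binarize_flow(comp, thr, exclude = combined)
  fd <- filter_small_deficits(fd, min_gld_um = cfg$filter$min_gld_um)
  list(fd_map = fd, combined_mask = combined, threshold = thr,
       compensated = comp)
}

#' Pipeline configuration
#'
#' @param compensation List: `mode` in `{"divide","complement","off"}`,
#'   `sigma_px`, `floor_quantile`.
#' @param fcm List: `max_iter`, `tol`.
#' @param filter List: `min_gld_um` (default 24).
#' @param vessel List: `threshold` (`"auto"` or numeric), `dilate_px`,
#'   optional pre-computed `mask`.
#' @param slab List of [slab_definition()] settings used when starting
#'   from a volume.
#' @return A list of class `quantify_config`.
#' @export
quantify_config <- function(compensation = list(),
                            fcm = list(),
                            filter = list(),
                            vessel = list(),
                            slab = list()) {
  cfg <- list(
    compensation = utils::modifyList(
      list(mode = "divide", sigma_px = 2, floor_quantile = 0.05), compensation),
    fcm = utils::modifyList(list(max_iter = 300L, tol = 1e-6), fcm),
    filter = utils::modifyList(list(min_gld_um = 24), filter),
    vessel = utils::modifyList(list(threshold = "auto", dilate_px = 1,
                                    mask = NULL), vessel),
    slab = utils::modifyList(list(cc_offset_um = 4, cc_thickness_um = 16,
                                  projection = "mean"), slab)
  )
  stopifnot(cfg$compensation$mode %in% c("divide", "complement", "off"))
  class(cfg) <- "quantify_config"
  cfg
}
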