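#' Merge exclusion masks into a combined mask
#'
#' Pixelwise union of all masks for one scan (HRF, calcified drusen,
#' hyperTDs, vessel projections, ...). Commutative and idempotent.
#'
#' @param masks Non-empty list of exclusion [binary_mask()]s with
#'   identical geometry.
#' @return A [binary_mask()] of kind `combined`.
#' @export
merge_masks <- function(masks) {
  if (!length(masks)) stop("merge_masks needs at least one mask", call. = FALSE)
  geom <- masks[[1L]]$geometry
  acc <- masks[[1L]]$pixels
  for (m in masks[-1L]) {
    check_geometry_match(geom, m$geometry, "masks")
    acc <- acc | m$pixels
  }
  binary_mask(acc, geom, kind = "combined")
}

#' Build the integrated mask across registered scans
#'
#' The integrated mask is the union of every scan's registered combined
#' mask together with the regions not covered by all scans (invalid after
#' registration), so that only areas with meaningful CC measurements in
#' every scan are compared. It is applied identically to every scan's
#' flow-deficit map.
#'
#' @param registered_combined Non-empty list of combined exclusion
#'   [binary_mask()]s, already in the baseline frame.
#' @param validity Optional list of validity [binary_mask()]s from
#'   [apply_transform()] (`TRUE` = covered); their complements are added
#'   to the integrated mask.
#' @return A [binary_mask()] of kind `integrated`.
#' @export
build_integrated_mask <- function(registered_combined, validity = list()) {
  if (!length(registered_combined)) {
    stop("build_integrated_mask needs at least one combined mask", call. = FALSE)
  }
  geom <- registered_combined[[1L]]$geometry
  acc <- Reduce(`|`, lapply(registered_combined, function(m) {
    check_geometry_match(geom, m$geometry, "combined masks")
    m$pixels
  }))
  for (v in validity) {
    check_geometry_match(geom, v$geometry, "validity masks")
    acc <- acc | !v$pixels
  }
  binary_mask(acc, geom, kind = "integrated")
}

#' Build a target-centered grid of complete boxes
#'
#' A target box of `box_size_px` pixels a side is centered on the target
#' pixel (fovea, or a druse for change analyses); boxes of equal size are
#' then propagated outward on the lattice to the edges of the registered
#' scan region. A box is retained only if it is complete: every pixel in
#' scan bounds and inside the validity region. With an even box size the
#' centre box is anchored at `center - floor(size/2)`, so the target
#' pixel sits in the box's upper-left quadrant.
#'
#' @param center_px `(row, col)` target location, 0-based.
#' @param box_size_px Box side length in pixels (default 74, about
#'   0.9 mm at 12-um spacing).
#' @param validity A validity [binary_mask()] (`TRUE` = usable), e.g.
#'   the registered-overlap region. Masked lesions are not handled here:
#'   they enter through the valid-pixel denominator, not by dropping
#'   boxes.
#' @return An object of class `ccfd_grid` with a `boxes` data frame
#'   (`row_start`, `col_start`, 0-based; lattice indices `i`, `j`;
#'   `is_target`; `roi_id`).
#' @export
build_grid <- function(center_px, box_size_px = 74L, validity) {
  s <- as.integer(box_size_px)
  stopifnot(s >= 1L)
  geom <- validity$geometry
  h <- geom$height_px; w <- geom$width_px
  r0 <- round(center_px[1L]) - s %/% 2L
  c0 <- round(center_px[2L]) - s %/% 2L
  box_ok <- function(rs, cs) {
    if (rs < 0L || cs < 0L || rs + s > h || cs + s > w) return(FALSE)
    all(validity$pixels[(rs + 1L):(rs + s), (cs + 1L):(cs + s)])
  }
  if (!box_ok(r0, c0)) stop("target box does not fit", call. = FALSE)
  is_ <- seq.int(-ceiling(h / s), ceiling(h / s))
  js_ <- seq.int(-ceiling(w / s), ceiling(w / s))
  boxes <- expand.grid(i = is_, j = js_)
  boxes$row_start <- r0 + boxes$i * s
  boxes$col_start <- c0 + boxes$j * s
  keep <- mapply(box_ok, boxes$row_start, boxes$col_start)
  boxes <- boxes[keep, , drop = FALSE]
  boxes$is_target <- boxes$i == 0L & boxes$j == 0L
  boxes$roi_id <- sprintf("box_%+d%+d", boxes$i, boxes$j)
  boxes <- boxes[order(boxes$i, boxes$j), c("row_start", "col_start", "i", "j",
                                            "is_target", "roi_id")]
  rownames(boxes) <- NULL
  structure(list(boxes = boxes, center_px = as.numeric(center_px),
                 box_size_px = s, geometry = geom),
            class = "ccfd_grid")
}

#' @export
print.ccfd_grid <- function(x, ...) {
  cat(sprintf("<ccfd_grid> %d complete %d-px boxes (%.2f mm a side) around (%.0f, %.0f)\n",
              nrow(x$boxes), x$box_size_px,
              x$box_size_px * x$geometry$pixel_spacing_um / 1000,
              x$center_px[1L], x$center_px[2L]))
  invisible(x)
}

# logical raster for one grid box
box_pixels <- function(grid, k) {
  b <- grid$boxes[k, ]
  m <- matrix(FALSE, grid$geometry$height_px, grid$geometry$width_px)
  m[(b$row_start + 1L):(b$row_start + grid$box_size_px),
    (b$col_start + 1L):(b$col_start + grid$box_size_px)] <- TRUE
  m
}

#' Build a fovea-centered circular ROI
#'
#' A pixel belongs to the circle iff its centre lies within
#' `diameter_mm / 2` of the centre point (distances via the pixel
#' spacing). If the circle extends past the scan bounds it is clipped
#' with a warning and the clipped fraction is recorded.
#'
#' @param center_px `(row, col)` centre, 0-based (typically the fovea).
#' @param diameter_mm Circle diameter in mm (3 and 5 in the standard
#'   workflow).
#' @param geometry A [scan_geometry()].
#' @return A validity-role [binary_mask()] (`TRUE` = inside the circle)
#'   with attribute `clip_fraction`.
#' @export
build_circle_roi <- function(center_px, diameter_mm, geometry) {
  stopifnot(diameter_mm > 0)
  r_px <- (diameter_mm * 1000 / 2) / geometry$pixel_spacing_um
  h <- geometry$height_px; w <- geometry$width_px
  R <- matrix(0:(h - 1), h, w)
  C <- matrix(0:(w - 1), h, w, byrow = TRUE)
  inside <- (R - center_px[1L])^2 + (C - center_px[2L])^2 <= r_px^2
  # full-disc pixel count if the scan were unbounded
  pad <- ceiling(r_px) + 1
  Rf <- matrix(-pad:pad, 2 * pad + 1, 2 * pad + 1)
  Cf <- t(Rf)
  frac_r <- center_px[1L] - round(center_px[1L])
  frac_c <- center_px[2L] - round(center_px[2L])
  full <- sum((Rf - frac_r)^2 + (Cf - frac_c)^2 <= r_px^2)
  clip_fraction <- 1 - sum(inside) / full
  if (clip_fraction > 1e-12) {
    warning(sprintf("circle ROI clipped at scan bounds (%.1f%% outside)",
                    100 * clip_fraction), call. = FALSE)
  }
  out <- binary_mask(inside, geometry, kind = "validity")
  attr(out, "clip_fraction") <- clip_fraction
  attr(out, "diameter_mm") <- diameter_mm
  out
}

roi_measurement <- function(roi_id, fd_px, valid_px, total_px) {
  data.frame(
    roi_id = roi_id,
    ccfd_percent = if (valid_px > 0) 100 * fd_px / valid_px else NA_real_,
    valid_px = as.integer(valid_px),
    total_px = as.integer(total_px),
    valid_fraction = if (total_px > 0) valid_px / total_px else 0,
    stringsAsFactors = FALSE
  )
}

#' Compute CCFD% within an ROI
#'
#' CCFD% is 100 times the number of flow-deficit pixels over the number
#' of valid pixels (ROI pixels not excluded by the integrated mask). For
#' a whole grid the pixels of all retained boxes are pooled: the grid
#' total is a single region, not the mean of per-box percentages. A
#' fully masked ROI yields `NA` CCFD% (never silently 0).
#'
#' @param fd A filtered [flow_deficit_map()].
#' @param integrated The integrated exclusion [binary_mask()] (or any
#'   exclusion mask; use an empty mask for none).
#' @param roi A `ccfd_grid` (pooled total), a single-box selection
#'   `list(grid, k)` is not needed — pass the grid and `roi_id`, a
#'   circle [binary_mask()] from [build_circle_roi()], or `NULL` for the
#'   whole scan.
#' @param roi_id For a grid: `"total"` (default) or one box `roi_id`.
#' @return A one-row data frame (`roi_id`, `ccfd_percent`, `valid_px`,
#'   `total_px`, `valid_fraction`).
#' @export
compute_ccfd_percent <- function(fd, integrated, roi = NULL, roi_id = "total") {
  check_geometry_match(fd$geometry, integrated$geometry, "fd map and mask")
  roi_px <- if (is.null(roi)) {
    matrix(TRUE, fd$geometry$height_px, fd$geometry$width_px)
  } else if (inherits(roi, "ccfd_grid")) {
    if (identical(roi_id, "total")) {
      Reduce(`|`, lapply(seq_len(nrow(roi$boxes)), function(k) box_pixels(roi, k)))
    } else {
      k <- match(roi_id, roi$boxes$roi_id)
      if (is.na(k)) stop(sprintf("unknown grid box '%s'", roi_id), call. = FALSE)
      box_pixels(roi, k)
    }
  } else if (inherits(roi, "binary_mask")) {
    roi$pixels
  } else {
    stop("roi must be a ccfd_grid, a binary_mask ROI, or NULL", call. = FALSE)
  }
  label <- if (is.null(roi)) "scan" else if (inherits(roi, "binary_mask")) {
    d <- attr(roi, "diameter_mm")
    if (is.null(d)) "roi" else sprintf("circle_%gmm", d)
  } else roi_id
  valid <- roi_px & !integrated$pixels
  roi_measurement(label, sum(fd$pixels & valid), sum(valid), sum(roi_px))
}

#' Measure a set of repeat scans on a shared grid
#'
#' End-to-end measurement for one visit (or one longitudinal set): every
#' scan is quantified separately, the scans are registered to the first
#' on their retinal-vasculature images, a single integrated mask, grid
#' and fovea-centered circles are built in the baseline frame, and CCFD%
#' is measured per scan for every box, both circles and the pooled grid
#' total.
#'
#' @param scans List of scans; each a list with elements `flow`,
#'   `structure`, `retina` ([enface_image()]s), optional `masks` (list of
#'   exclusion masks) and `meta` ([scan_metadata()]).
#' @param fovea `(row, col)` grid/circle centre in the baseline frame;
#'   defaults to the baseline scan's fovea.
#' @param cfg A [quantify_config()].
#' @param box_size_px Grid box size (default 74).
#' @param circles_mm Circle diameters in mm (default `c(3, 5)`).
#' @param grid_center Optional override of the grid centre (e.g. a druse
#'   for target-box analyses); defaults to `fovea`.
#' @param registration List of extra arguments for [register_enface()].
#' @return A `measurement table` data frame with one row per (scan, ROI):
#'   ids, `roi_type`, `roi_id`, `ccfd_percent`, `valid_px`, `total_px`,
#'   `valid_fraction`; the grid descriptor is attached as attribute
#'   `grid`.
#' @export
measure_visit_set <- function(scans, fovea = NULL, cfg = quantify_config(),
                              box_size_px = 74L, circles_mm = c(3, 5),
                              grid_center = NULL, registration = list()) {
  stopifnot(length(scans) >= 1L)
  geom <- scans[[1L]]$flow$geometry
  if (is.null(fovea)) fovea <- geom$fovea_px
  if (is.null(grid_center)) grid_center <- fovea

  quant <- lapply(scans, function(sc) {
    quantify_scan(sc$flow, sc$structure, sc$retina,
                  masks = if (is.null(sc$masks)) list() else sc$masks,
                  cfg = cfg)
  })

  all_valid <- binary_mask(matrix(TRUE, geom$height_px, geom$width_px),
                           geom, kind = "validity")
  fd_maps <- vector("list", length(scans))
  combined <- vector("list", length(scans))
  validity <- vector("list", length(scans))
  fd_maps[[1L]] <- quant[[1L]]$fd_map
  combined[[1L]] <- quant[[1L]]$combined_mask
  validity[[1L]] <- all_valid
  if (length(scans) > 1L) {
    for (k in 2:length(scans)) {
      t_k <- tryCatch(
        do.call(register_enface,
                c(list(moving = scans[[k]]$retina, fixed = scans[[1L]]$retina),
                  registration)),
        error = function(e) {
          id <- if (!is.null(scans[[k]]$meta)) {
            sprintf("%s/%s/r%d", scans[[k]]$meta$eye_id,
                    scans[[k]]$meta$visit_id, scans[[k]]$meta$repeat_index)
          } else sprintf("scan %d", k)
          stop(sprintf("registration failed for %s: %s", id,
                       conditionMessage(e)), call. = FALSE)
        })
      tf <- apply_transform(quant[[k]]$fd_map, t_k)
      tm <- apply_transform(quant[[k]]$combined_mask, t_k)
      fd_maps[[k]] <- tf$result
      combined[[k]] <- tm$result
      validity[[k]] <- tf$validity
    }
  }
  integrated <- build_integrated_mask(combined, validity)
  overlap <- binary_mask(Reduce(`&`, lapply(validity, `[[`, "pixels")),
                         geom, kind = "validity")
  grid <- build_grid(grid_center, box_size_px, overlap)
  circ <- lapply(circles_mm, function(d) build_circle_roi(fovea, d, geom))

  rows <- list()
  for (k in seq_along(scans)) {
    meta <- scans[[k]]$meta
    ids <- data.frame(
      patient_id = if (is.null(meta)) NA_character_ else meta$patient_id,
      eye_id = if (is.null(meta)) NA_character_ else meta$eye_id,
      visit_id = if (is.null(meta)) NA_character_ else meta$visit_id,
      repeat_index = if (is.null(meta)) k else meta$repeat_index,
      group_label = if (is.null(meta)) "unspecified" else meta$group_label,
      stringsAsFactors = FALSE
    )
    for (ci in seq_along(circ)) {
      m <- compute_ccfd_percent(fd_maps[[k]], integrated, circ[[ci]])
      rows[[length(rows) + 1L]] <- cbind(ids, roi_type = "circle", m)
    }
    for (b in grid$boxes$roi_id) {
      m <- compute_ccfd_percent(fd_maps[[k]], integrated, grid, roi_id = b)
      rows[[length(rows) + 1L]] <- cbind(ids, roi_type = "box", m)
    }
    m <- compute_ccfd_percent(fd_maps[[k]], integrated, grid, roi_id = "total")
    m$roi_id <- "grid_total"
    rows[[length(rows) + 1L]] <- cbind(ids, roi_type = "grid_total", m)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "grid") <- grid
  attr(out, "integrated_mask") <- integrated
  out
}
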