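#' Synthetic-eye simulation configuration
#'
#' Defines the study conditions emulated by the generator: a 500 x 500-px
#' en-face raster at 12-um spacing (the nominal 6-mm x 6-mm scan
#' pattern), flow-deficit texture with a correlation length on the scale
#' of the choriocapillaris intercapillary distance, multiplicative
#' drusen shadowing shared by the flow and structure channels, lesion
#' masks, a branching retinal vessel tree for registration landmarks,
#' repeat-scan noise and inter-scan misalignment.
#'
#' @param size_px Image side in pixels (default 500).
#' @param pixel_spacing_um Lateral spacing in um (default 12).
#' @param fd_density Target flow-deficit area fraction in (0, 0.5)
#'   (default 0.08, the CCFD% scale seen in healthy maculae).
#' @param fd_blob_scale_um Correlation length of the deficit texture in
#'   um (default 30, comparable to the CC intercapillary distance).
#' @param fd_contrast Fractional flow drop inside a deficit (default 0.5,
#'   chosen so acquisition and repeat noise produce nonzero test-retest
#'   variability of CCFD%, as real scans do, while keeping enough
#'   deficit/background separation that compensated shadow regions are
#'   not dominated by amplified noise).
#' @param base_flow,base_structure Mean intensity of the flow /
#'   structure channels (default 120 / 140 on the 8-bit-like scale).
#' @param noise_sd Additive acquisition noise SD (default 8).
#' @param drusen List of drusen, each
#'   `list(center_px = c(row, col), radius_um = ..., attenuation = a)`
#'   with attenuation factor `a` in (0, 1] (1 = no shadowing).
#' @param lesions Named list of lesion blob counts per mask kind, e.g.
#'   `list(hrf = 2, cad = 1)`; each becomes a small disc exclusion mask.
#' @param lesion_radius_um Radius of lesion blobs (default 120).
#' @param vessel_depth Recursion depth of the retinal vessel tree
#'   (default 7).
#' @param repeat_noise_sd Additional per-repeat noise SD (default 6).
#' @param misalign_max_px Repeat misalignment: integer shifts drawn
#'   uniformly from `[-misalign_max_px, misalign_max_px]` per axis
#'   (default 6); rotation is not simulated by default.
#' @param seed Integer RNG seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(size_px = 500L, pixel_spacing_um = 12,
                              fd_density = 0.08, fd_blob_scale_um = 30,
                              fd_contrast = 0.5, base_flow = 120,
                              base_structure = 140, noise_sd = 8,
                              drusen = list(), lesions = list(),
                              lesion_radius_um = 120, vessel_depth = 7L,
                              repeat_noise_sd = 6, misalign_max_px = 6L,
                              seed = 1L) {
  if (fd_density <= 0 || fd_density >= 0.5) {
    stop("fd_density must lie in (0, 0.5)", call. = FALSE)
  }
  stopifnot(fd_blob_scale_um > 0, pixel_spacing_um > 0, size_px >= 64L)
  for (d in drusen) {
    stopifnot(d$attenuation > 0, d$attenuation <= 1, d$radius_um > 0)
  }
  structure(as.list(environment()), class = "simulation_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv())) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed(seed)
  force(code)
}

# smooth-edged attenuation field: 1 everywhere, dipping to each druse's
# attenuation factor inside its disc
attenuation_field <- function(cfg, drusen = cfg$drusen) {
  n <- cfg$size_px
  field <- matrix(1, n, n)
  for (d in drusen) {
    r_px <- d$radius_um / cfg$pixel_spacing_um
    R <- matrix(0:(n - 1), n, n); C <- t(R)
    disc <- ((R - d$center_px[1L])^2 + (C - d$center_px[2L])^2 <= r_px^2) * 1
    disc <- gaussian_blur(disc, sigma = max(2, r_px / 8))
    field <- field * (1 - (1 - d$attenuation) * pmin(disc, 1))
  }
  field
}

render_vessel_tree <- function(cfg) {
  n <- cfg$size_px
  img <- matrix(0, n, n)
  splat <- function(r, c, width) {
    ri <- round(r) + 1L; ci <- round(c) + 1L
    wpx <- max(1L, round(width))
    rs <- max(1L, ri - wpx):min(n, ri + wpx)
    cs <- max(1L, ci - wpx):min(n, ci + wpx)
    img[rs, cs] <<- pmax(img[rs, cs], 1)
  }
  draw_branch <- function(r, c, angle, len, width, depth) {
    if (depth <= 0L || len < 4) return(invisible())
    steps <- seq(0, len, by = 1)
    rr <- r + steps * sin(angle)
    cc <- c + steps * cos(angle)
    ok <- rr >= 0 & rr < n & cc >= 0 & cc < n
    for (s in which(ok)) splat(rr[s], cc[s], width)
    r2 <- r + len * sin(angle); c2 <- c + len * cos(angle)
    spread <- stats::runif(2, 0.25, 0.6)
    draw_branch(r2, c2, angle + spread[1L], len * 0.72, width * 0.8, depth - 1L)
    draw_branch(r2, c2, angle - spread[2L], len * 0.72, width * 0.8, depth - 1L)
  }
  # four arcade roots entering from the nasal edge midpoints
  roots <- list(c(n * 0.5, 0, 0.4), c(n * 0.5, 0, -0.4),
                c(0, n * 0.5, pi / 2 - 0.9), c(n - 1, n * 0.5, -pi / 2 + 0.9))
  for (rt in roots) {
    draw_branch(rt[1L], rt[2L], rt[3L], n * 0.3, 2.2, cfg$vessel_depth)
  }
  img <- gaussian_blur(img, 1.5)
  img / max(img)
}

#' Simulate one synthetic eye with known ground truth
#'
#' The true deficit field is thresholded correlated Gaussian noise, so
#' the deficit fraction is exact by construction. Flow is the base level
#' darkened inside deficits, multiplied by the shared drusen attenuation
#' field, plus noise; structure is its base level times the same
#' attenuation field plus noise; the retinal channel is a rendered
#' branching vessel tree. Deterministic given the config seed.
#'
#' @param cfg A [simulation_config()].
#' @return A list: `flow`, `structure`, `retina` ([enface_image()]s),
#'   `masks` (named list of exclusion [binary_mask()]s), and `truth`
#'   (`true_fd_map`, `attenuation_field`, `fovea_px`, and
#'   `true_ccfd_percent(roi_pixels)` helper-free raster for truth
#'   recomputation).
#' @export
simulate_eye <- function(cfg = simulation_config()) {
  with_seed(cfg$seed, {
    n <- cfg$size_px
    geom <- scan_geometry(n, n, cfg$pixel_spacing_um,
                          fovea_px = c((n - 1) / 2, (n - 1) / 2))
    sigma_px <- cfg$fd_blob_scale_um / cfg$pixel_spacing_um
    field <- gaussian_blur(matrix(stats::rnorm(n * n), n, n), sigma_px)
    cut <- stats::quantile(field, 1 - cfg$fd_density, names = FALSE)
    true_fd <- field > cut
    atten <- attenuation_field(cfg)
    flow_px <- cfg$base_flow * (1 - true_fd * cfg$fd_contrast) * atten +
      stats::rnorm(n * n, sd = cfg$noise_sd)
    struct_px <- cfg$base_structure * atten +
      stats::rnorm(n * n, sd = cfg$noise_sd)
    retina_px <- 10 + 190 * render_vessel_tree(cfg) +
      stats::rnorm(n * n, sd = 3)
    masks <- list()
    for (kind in names(cfg$lesions)) {
      cnt <- cfg$lesions[[kind]]
      if (cnt < 1L) next
      m <- matrix(FALSE, n, n)
      r_px <- cfg$lesion_radius_um / cfg$pixel_spacing_um
      centers <- cbind(stats::runif(cnt, n * 0.15, n * 0.85),
                       stats::runif(cnt, n * 0.15, n * 0.85))
      R <- matrix(0:(n - 1), n, n); C <- t(R)
      for (i in seq_len(cnt)) {
        m <- m | ((R - centers[i, 1L])^2 + (C - centers[i, 2L])^2 <= r_px^2)
      }
      masks[[kind]] <- binary_mask(m, geom, kind = kind)
    }
    truth <- list(true_fd_map = true_fd, attenuation_field = atten,
                  fovea_px = geom$fovea_px,
                  fd_density = cfg$fd_density, config = cfg)
    list(flow = enface_image(pmax(flow_px, 0), geom, "cc_flow"),
         structure = enface_image(pmax(struct_px, 0), geom, "cc_structure"),
         retina = enface_image(pmax(retina_px, 0), geom, "retinal_vasculature"),
         masks = masks, truth = truth)
  })
}

#' True CCFD% of a simulated eye within an ROI
#'
#' Recomputes the generator ground truth by the same pixel-count rule
#' the pipeline uses: 100 x deficit pixels / ROI pixels.
#'
#' @param truth The `truth` element of [simulate_eye()].
#' @param roi_pixels Logical matrix selecting the ROI (default: whole
#'   scan).
#' @return True CCFD% in the ROI.
#' @export
true_ccfd_percent <- function(truth, roi_pixels = NULL) {
  fd <- truth$true_fd_map
  if (is.null(roi_pixels)) roi_pixels <- matrix(TRUE, nrow(fd), ncol(fd))
  100 * sum(fd & roi_pixels) / sum(roi_pixels)
}

#' Simulate same-day repeat scans of one eye
#'
#' Each repeat shares the eye's ground truth and adds independent
#' acquisition noise (`repeat_noise_sd`) to every channel plus a random
#' integer-pixel rigid misalignment; the first repeat is the aligned
#' baseline. True misalignments are recorded for registration checks.
#'
#' @param eye A [simulate_eye()] result.
#' @param n Number of repeats (>= 2; the standard protocol uses 3).
#' @param cfg The [simulation_config()] (defaults to the eye's).
#' @param meta_base Optional [scan_metadata()] template; `repeat_index`
#'   is filled per repeat.
#' @return A list of scans (each `flow`/`structure`/`retina`/`masks`/
#'   `meta`), with the list of true [rigid_transform()]s as attribute
#'   `true_transforms`.
#' @export
simulate_repeats <- function(eye, n = 3L, cfg = eye$truth$config,
                             meta_base = NULL) {
  stopifnot(n >= 2L)
  with_seed(cfg$seed + 7919L, {
    scans <- vector("list", n)
    transforms <- vector("list", n)
    for (k in seq_len(n)) {
      t_k <- if (k == 1L) rigid_transform(0, 0, 0) else {
        rigid_transform(sample(-cfg$misalign_max_px:cfg$misalign_max_px, 1L),
                        sample(-cfg$misalign_max_px:cfg$misalign_max_px, 1L), 0)
      }
      transforms[[k]] <- t_k
      jitter <- function(img) {
        px <- img$pixels
        if (cfg$repeat_noise_sd > 0) {
          px <- pmax(px + stats::rnorm(length(px), sd = cfg$repeat_noise_sd), 0)
        }
        out <- enface_image(px, img$geometry, img$channel)
        if (t_k$dx_px != 0 || t_k$dy_px != 0) {
          out <- apply_transform(out, t_k)$result
        }
        out
      }
      masks_k <- lapply(eye$masks, function(m) {
        if (t_k$dx_px != 0 || t_k$dy_px != 0) apply_transform(m, t_k)$result else m
      })
      meta <- if (is.null(meta_base)) {
        scan_metadata("p1", "e1", "v1", repeat_index = k, signal_strength = 9L)
      } else {
        scan_metadata(meta_base$patient_id, meta_base$eye_id,
                      meta_base$visit_id, repeat_index = k,
                      signal_strength = meta_base$signal_strength,
                      group_label = meta_base$group_label)
      }
      scans[[k]] <- list(flow = jitter(eye$flow),
                         structure = jitter(eye$structure),
                         retina = jitter(eye$retina),
                         masks = masks_k, meta = meta)
    }
    attr(scans, "true_transforms") <- transforms
    scans
  })
}

#' Simulate a drusen-resolution visit pair
#'
#' Baseline scans carry the druse's multiplicative shadow; at follow-up
#' the druse has resolved without anatomic sequelae, i.e. its
#' attenuation is removed while the true flow-deficit field is
#' unchanged. The grid target box for change analysis is the box
#' centered on the druse.
#'
#' @param eye A [simulate_eye()] result whose config contains at least
#'   one druse.
#' @param druse_id Index into `cfg$drusen` (default 1).
#' @param n_repeats Scans per visit (default 1; the change analysis
#'   needs one map per visit).
#' @return A list: `baseline` and `followup` scan sets (as in
#'   [simulate_repeats()] but allowing `n_repeats = 1`),
#'   `target_center_px` (druse centre, the grid centre for the change
#'   analysis) and `druse`.
#' @export
simulate_drusen_resolution_pair <- function(eye, druse_id = 1L, n_repeats = 1L) {
  cfg <- eye$truth$config
  if (druse_id < 1L || druse_id > length(cfg$drusen)) {
    stop(sprintf("unknown druse_id %s (eye has %d drusen)",
                 druse_id, length(cfg$drusen)), call. = FALSE)
  }
  druse <- cfg$drusen[[druse_id]]
  cfg_fu <- cfg
  cfg_fu$drusen <- cfg$drusen[-druse_id]
  cfg_fu$seed <- cfg$seed + 104729L  # new acquisition, same truth field
  # rebuild the follow-up images from the same truth with the druse gone
  with_seed(cfg_fu$seed, {
    n <- cfg$size_px
    geom <- eye$flow$geometry
    atten_fu <- attenuation_field(cfg_fu)
    true_fd <- eye$truth$true_fd_map
    flow_px <- cfg$base_flow * (1 - true_fd * cfg$fd_contrast) * atten_fu +
      stats::rnorm(n * n, sd = cfg$noise_sd)
    struct_px <- cfg$base_structure * atten_fu +
      stats::rnorm(n * n, sd = cfg$noise_sd)
    retina_px <- eye$retina$pixels + stats::rnorm(n * n, sd = 3)
    followup_eye <- list(
      flow = enface_image(pmax(flow_px, 0), geom, "cc_flow"),
      structure = enface_image(pmax(struct_px, 0), geom, "cc_structure"),
      retina = enface_image(pmax(retina_px, 0), geom, "retinal_vasculature"),
      masks = eye$masks,
      truth = list(true_fd_map = true_fd, attenuation_field = atten_fu,
                   fovea_px = geom$fovea_px, fd_density = cfg$fd_density,
                   config = cfg_fu)
    )
    wrap <- function(e, visit, nrep) {
      if (nrep >= 2L) {
        simulate_repeats(e, nrep, e$truth$config,
                         meta_base = scan_metadata("p1", "e1", visit,
                                                   signal_strength = 9L))
      } else {
        sc <- list(list(flow = e$flow, structure = e$structure,
                        retina = e$retina, masks = e$masks,
                        meta = scan_metadata("p1", "e1", visit,
                                             signal_strength = 9L)))
        attr(sc, "true_transforms") <- list(rigid_transform(0, 0, 0))
        sc
      }
    }
    list(baseline = wrap(eye, "baseline", n_repeats),
         followup = wrap(followup_eye, "followup", n_repeats),
         target_center_px = druse$center_px,
         druse = druse)
  })
}

#' Default drusen-resolution study configuration
#'
#' A multifocal intermediate-AMD-like macula on the standard
#' 500-px / 12-um raster: a large resolving druse (radius 300 um,
#' attenuation factor 0.5) off the fovea as druse 1, plus eleven
#' persistent drusen (radius 250 um, attenuation 0.45) scattered across
#' the scan. Drusen in intermediate AMD are multifocal, and the
#' persistent drusen matter quantitatively: the structure-image
#' compensation floor is a low quantile of the structure intensities,
#' so the attenuated end of the intensity distribution must carry
#' realistic mass for shadowed regions to be divided by their true
#' attenuated structure level rather than by the floor.
#'
#' @param seed Integer RNG seed.
#' @return A [simulation_config()] whose druse 1 is the resolving druse.
#' @export
drusen_resolution_config <- function(seed = 1L) {
  persistent_centers <- list(
    c(80, 300), c(80, 420), c(200, 420), c(330, 80), c(330, 230),
    c(330, 380), c(430, 150), c(430, 300), c(430, 430), c(70, 70),
    c(250, 250))
  simulation_config(
    drusen = c(
      list(list(center_px = c(150, 150), radius_um = 300, attenuation = 0.5)),
      lapply(persistent_centers, function(ct) {
        list(center_px = ct, radius_um = 250, attenuation = 0.45)
      })),
    seed = seed
  )
}
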