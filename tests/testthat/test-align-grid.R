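test_that("registration recovers identity and known integer shifts exactly", {
  ret <- fixture_retina(96)
  t0 <- register_enface(ret, ret)
  expect_equal(c(t0$dx_px, t0$dy_px, t0$theta_deg), c(0, 0, 0))
  expect_equal(t0$score, 1.0, tolerance = 1e-12)

  for (shift in list(c(7, -3), c(-5, 11), c(0, 9))) {
    t_fwd <- rigid_transform(shift[1L], shift[2L])
    moved <- apply_transform(ret, t_fwd)$result
    t_est <- register_enface(moved, ret)
    # estimated transform maps the moved scan back onto the baseline
    expect_equal(c(t_est$dx_px, t_est$dy_px), -shift)
  }
})

test_that("rotation search recovers a known small rotation", {
  ret <- fixture_retina(96)
  t_true <- rigid_transform(3, -2, 1)
  moved <- apply_transform(ret, t_true)$result
  t_est <- register_enface(moved, ret, rotation = TRUE, rot_range_deg = 2,
                           rot_step_deg = 0.25)
  expect_lte(abs(t_est$theta_deg - (-1)), 0.25)
})

test_that("registration failure below the score floor is an error", {
  set.seed(2)
  g <- tiny_geometry(64)
  a <- enface_image(matrix(runif(64 * 64), 64), g, "retinal_vasculature")
  b <- enface_image(matrix(runif(64 * 64), 64), g, "retinal_vasculature")
  expect_error(register_enface(a, b, min_score = 0.9), "registration failed")
})

test_that("apply_transform has exact inverses and closed-form validity counts", {
  g <- tiny_geometry(80)
  set.seed(8)
  bin <- binary_mask(matrix(runif(6400) < 0.2, 80), g, kind = "hrf")
  idt <- apply_transform(bin, rigid_transform(0, 0, 0))
  expect_identical(idt$result$pixels, bin$pixels)
  expect_true(all(idt$validity$pixels))

  fwd <- apply_transform(bin, rigid_transform(7, -3))
  back <- apply_transform(fwd$result, rigid_transform(-7, 3))
  joint <- apply_transform(fwd$validity, rigid_transform(-7, 3))
  ok <- joint$result$pixels & joint$validity$pixels
  expect_identical(back$result$pixels[ok], bin$pixels[ok])

  # validity count after pure shift: (H - |dy|) x (W - |dx|)
  for (shift in list(c(4, 9), c(-6, 2), c(0, -13))) {
    v <- apply_transform(bin, rigid_transform(shift[1L], shift[2L]))$validity
    expect_equal(sum(v$pixels),
                 (80 - abs(shift[2L])) * (80 - abs(shift[1L])))
  }
})

test_that("mask merging is a commutative idempotent union", {
  g <- tiny_geometry(30)
  a <- matrix(FALSE, 30, 30); a[1:5, 1:5] <- TRUE
  b <- matrix(FALSE, 30, 30); b[20:25, 20:25] <- TRUE
  ma <- binary_mask(a, g, kind = "hrf"); mb <- binary_mask(b, g, kind = "cad")
  u <- merge_masks(list(ma, mb))
  expect_equal(sum(u$pixels), sum(a) + sum(b))  # disjoint
  expect_identical(merge_masks(list(ma))$pixels, a)
  expect_identical(merge_masks(list(ma, mb))$pixels,
                   merge_masks(list(mb, ma))$pixels)
  expect_identical(merge_masks(list(ma, ma))$pixels, a)
  expect_error(merge_masks(list(ma, binary_mask(matrix(FALSE, 10, 10),
                                                tiny_geometry(10), "hrf"))),
               "geometry mismatch")
  expect_error(merge_masks(list()), "at least one")
})

test_that("integrated mask covers all combined masks and non-overlap regions", {
  g <- tiny_geometry(50)
  a <- matrix(FALSE, 50, 50); a[1:3, ] <- TRUE
  b <- matrix(FALSE, 50, 50); b[, 1:3] <- TRUE
  ma <- binary_mask(a, g); mb <- binary_mask(b, g)
  # single scan, all valid -> integrated == its combined mask
  expect_identical(build_integrated_mask(list(ma))$pixels, a)
  # disjoint-ish masks -> union
  expect_identical(build_integrated_mask(list(ma, mb))$pixels, a | b)
  # 10-px shift leaves a 10-px invalid strip that must be excluded
  v <- apply_transform(binary_mask(matrix(FALSE, 50, 50), g),
                       rigid_transform(10, 0))$validity
  integ <- build_integrated_mask(list(binary_mask(matrix(FALSE, 50, 50), g)),
                                 list(v))
  expect_equal(sum(integ$pixels), 50 * 10)
  expect_error(build_integrated_mask(list()), "at least one")
})

test_that("fovea-centered grid yields 25 boxes on a full 500-px scan and 36 at best offset", {
  g <- scan_geometry(500, 500, 12, fovea_px = c(250, 250))
  validity <- all_valid_mask(g)
  grid <- build_grid(c(250, 250), 74L, validity)
  expect_equal(nrow(grid$boxes), 25L)
  expect_equal(sum(grid$boxes$is_target), 1L)
  # boxes tile without overlap and stay in bounds
  expect_true(all(grid$boxes$row_start >= 0 & grid$boxes$row_start + 74 <= 500))
  cov <- matrix(0L, 500, 500)
  for (k in seq_len(nrow(grid$boxes))) {
    b <- grid$boxes[k, ]
    cov[(b$row_start + 1):(b$row_start + 74),
        (b$col_start + 1):(b$col_start + 74)] <-
      cov[(b$row_start + 1):(b$row_start + 74),
          (b$col_start + 1):(b$col_start + 74)] + 1L
  }
  expect_lte(max(cov), 1L)

  # sweeping the anchor finds the 36-box packing
  best <- 0L
  for (r0 in 0:73) for (c0 in 0:73) {
    nb <- floor((500 - r0) / 74) * floor((500 - c0) / 74)
    if (nb > best) best <- nb
  }
  counts <- vapply(0:73, function(off) {
    ctr <- c(off + 37, off + 37)
    nrow(build_grid(ctr, 74L, validity)$boxes)
  }, integer(1L))
  expect_equal(max(counts), 36L)
  expect_equal(max(counts), best)

  # grid area: 25 boxes x (74 x 12 um)^2 = 19.71 mm^2
  area_mm2 <- nrow(grid$boxes) * (74 * 12 / 1000)^2
  expect_equal(round(area_mm2, 2), 19.71)
  # a validity region smaller than one box cannot host the target box
  small <- binary_mask(matrix(FALSE, 500, 500), g, kind = "validity")
  small$pixels[1:60, 1:60] <- TRUE
  expect_error(build_grid(c(30, 30), 74L, small), "target box does not fit")
})

test_that("circle ROIs have the right area and scale quadratically", {
  g <- scan_geometry(500, 500, 12, fovea_px = c(250, 250))
  c5 <- build_circle_roi(c(250, 250), 5, g)
  expect_lt(abs(sum(c5$pixels) * 0.012^2 - 19.63) / 19.63, 0.005)
  expect_equal(attr(c5, "clip_fraction"), 0)
  # diameter equal to two pixel spacings: centre + 4-neighbourhood
  tiny <- build_circle_roi(c(250, 250), 0.024, g)
  expect_equal(sum(tiny$pixels), 5L)
  # doubling the diameter quadruples the area within discretisation error
  c25 <- build_circle_roi(c(250, 250), 2.5, g)
  expect_lt(abs(sum(c5$pixels) / sum(c25$pixels) - 4), 0.05)
  # clipping warns and reports the outside fraction
  expect_warning(cc <- build_circle_roi(c(10, 10), 5, g), "clipped")
  expect_gt(attr(cc, "clip_fraction"), 0.5)
})

test_that("CCFD% matches the pixel-loop oracle and pools grid pixels", {
  g <- tiny_geometry(100)
  set.seed(55)
  fd <- flow_deficit_map(matrix(runif(1e4) < 0.12, 100), g)
  excl <- binary_mask(matrix(runif(1e4) < 0.2, 100), g)
  roi <- matrix(FALSE, 100, 100); roi[11:84, 11:84] <- TRUE

  m <- compute_ccfd_percent(fd, excl,
                            binary_mask(roi, g, kind = "validity"))
  expect_equal(m$ccfd_percent, oracle_ccfd_percent(fd$pixels, excl$pixels, roi))
  expect_equal(m$valid_px + sum(roi & excl$pixels), m$total_px)

  # empty fd -> 0%
  m0 <- compute_ccfd_percent(flow_deficit_map(matrix(FALSE, 100, 100), g), excl)
  expect_equal(m0$ccfd_percent, 0)

  # fully masked ROI -> NA, not 0
  allm <- binary_mask(matrix(TRUE, 100, 100), g)
  mna <- compute_ccfd_percent(fd, allm)
  expect_true(is.na(mna$ccfd_percent))
  expect_equal(mna$valid_fraction, 0)

  # grid total pools pixels; differs from the mean of box percentages
  # when boxes are unequally masked: all deficits sit in one box that is
  # 90% masked, so the box mean far exceeds the pooled value
  gg <- scan_geometry(60, 60, 12)
  grid <- build_grid(c(30, 30), 20L, all_valid_mask(gg))
  fd2px <- matrix(FALSE, 60, 60)
  fd2px[1:20, 1:20] <- TRUE
  fd2 <- flow_deficit_map(fd2px, gg)
  ex2px <- matrix(FALSE, 60, 60); ex2px[1:20, 1:18] <- TRUE
  ex2 <- binary_mask(ex2px, gg)
  total <- compute_ccfd_percent(fd2, ex2, grid, roi_id = "total")
  per_box <- vapply(grid$boxes$roi_id, function(b) {
    compute_ccfd_percent(fd2, ex2, grid, roi_id = b)$ccfd_percent
  }, numeric(1L))
  pooled_oracle <- {
    roi_all <- matrix(FALSE, 60, 60)
    for (k in seq_len(nrow(grid$boxes))) {
      b <- grid$boxes[k, ]
      roi_all[(b$row_start + 1):(b$row_start + 20),
              (b$col_start + 1):(b$col_start + 20)] <- TRUE
    }
    oracle_ccfd_percent(fd2px, ex2px, roi_all)
  }
  expect_equal(total$ccfd_percent, pooled_oracle)
  expect_gt(abs(total$ccfd_percent - mean(per_box, na.rm = TRUE)), 0.1)
})

test_that("CCFD% is invariant under joint translation of map, mask and ROI", {
  g <- tiny_geometry(80)
  set.seed(66)
  fd <- flow_deficit_map(matrix(runif(6400) < 0.1, 80), g)
  ex <- binary_mask(matrix(runif(6400) < 0.15, 80), g)
  roi <- matrix(FALSE, 80, 80); roi[21:50, 21:50] <- TRUE
  t <- rigid_transform(5, 8)
  m1 <- compute_ccfd_percent(fd, ex, binary_mask(roi, g, kind = "validity"))
  m2 <- compute_ccfd_percent(
    apply_transform(fd, t)$result,
    apply_transform(ex, t)$result,
    binary_mask(apply_transform(binary_mask(roi, g, kind = "validity"), t)$result$pixels,
                g, kind = "validity"))
  expect_equal(m1$ccfd_percent, m2$ccfd_percent)
})

test_that("measure_visit_set gives identical rows for identical repeats and survives shifts", {
  cfg <- simulation_config(size_px = 160, repeat_noise_sd = 0,
                           misalign_max_px = 0L, seed = 12)
  eye <- simulate_eye(cfg)
  scans <- simulate_repeats(eye, 3, cfg)
  tab <- suppressWarnings(measure_visit_set(scans))
  gt <- tab[tab$roi_id == "grid_total", "ccfd_percent"]
  expect_equal(length(unique(gt)), 1L)  # no noise, no shift -> identical

  # repeats that are circular shifts of the baseline (identical content,
  # different alignment) give identical per-box values after
  # registration, because thresholding sees the same distribution
  circ_shift <- function(m, dy, dx) {
    h <- nrow(m); w <- ncol(m)
    m[((seq_len(h) - 1 - dy) %% h) + 1, ((seq_len(w) - 1 - dx) %% w) + 1]
  }
  mk_shifted <- function(base, dy, dx) {
    list(flow = enface_image(circ_shift(base$flow$pixels, dy, dx),
                             base$flow$geometry, "cc_flow"),
         structure = enface_image(circ_shift(base$structure$pixels, dy, dx),
                                  base$structure$geometry, "cc_structure"),
         retina = enface_image(circ_shift(base$retina$pixels, dy, dx),
                               base$retina$geometry, "retinal_vasculature"),
         masks = list(), meta = NULL)
  }
  base <- scans[[1]]
  scans2 <- list(base, mk_shifted(base, 3, -4), mk_shifted(base, -2, 5))
  # fixed empty vessel mask so every repeat is thresholded on exactly the
  # same intensity distribution (edge dilation effects excluded)
  no_vessels <- binary_mask(matrix(FALSE, 160, 160), base$flow$geometry,
                            kind = "vessel_projection")
  tab2 <- suppressWarnings(measure_visit_set(
    scans2, cfg = quantify_config(vessel = list(mask = no_vessels))))
  box2 <- tab2[tab2$roi_type == "box", ]
  sp <- split(box2$ccfd_percent, box2$roi_id)
  for (vals in sp) expect_lt(max(vals) - min(vals), 1e-9)
})
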