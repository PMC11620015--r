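# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the full suite stays fast.

tiny_geometry <- function(n = 64L, spacing = 12) scan_geometry(n, n, spacing)

# deterministic pseudo-vasculature image: bright smooth ridges on a dark
# background, enough texture for correlation registration
fixture_retina <- function(n = 96L, seed = 101L) {
  set.seed(seed)
  px <- matrix(pmax(0, stats::rnorm(n * n, 40, 15)), n)
  px[, seq(10L, n, by = 17L)] <- px[, seq(10L, n, by = 17L)] + 160
  px[seq(7L, n, by = 23L), ] <- px[seq(7L, n, by = 23L), ] + 140
  enface_image(px, tiny_geometry(n), "retinal_vasculature")
}

all_valid_mask <- function(geom) {
  binary_mask(matrix(TRUE, geom$height_px, geom$width_px), geom,
              kind = "validity")
}

# brute-force oracle: surviving pixels after the GLD size filter,
# enumerating 8-connected components by BFS and all pixel pairs
oracle_gld_filter <- function(fd, spacing_um, min_gld_um) {
  h <- nrow(fd); w <- ncol(fd)
  seen <- matrix(FALSE, h, w)
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!fd[r, c] || seen[r, c]) next
    queue <- list(c(r, c)); seen[r, c] <- TRUE; comp <- list()
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      comp[[length(comp) + 1L]] <- p
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1L] + dr; cc <- p[2L] + dc
        if (rr >= 1L && rr <= h && cc >= 1L && cc <= w &&
            fd[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
    pts <- do.call(rbind, comp)
    gld <- if (nrow(pts) == 1L) spacing_um else {
      dmax <- 0
      for (i in seq_len(nrow(pts) - 1L)) for (j in (i + 1L):nrow(pts)) {
        d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
        if (d > dmax) dmax <- d
      }
      dmax * spacing_um + spacing_um
    }
    if (gld >= min_gld_um) for (p in comp) out[p[1L], p[2L]] <- TRUE
  }
  out
}

# unbinned fuzzy C-means oracle on raw pixel values (m = 2)
oracle_fcm_unbinned <- function(vals, tol = 1e-9, max_iter = 1000L) {
  centers <- stats::quantile(vals, c(0.1, 0.9), names = FALSE)
  c1 <- centers[1L]; c2 <- centers[2L]
  for (it in seq_len(max_iter)) {
    d1 <- (vals - c1)^2; d2 <- (vals - c2)^2
    u1 <- ifelse(d1 == 0, 1, ifelse(d2 == 0, 0, d2 / (d1 + d2)))
    u2 <- 1 - u1
    n1 <- sum(u1^2); n2 <- sum(u2^2)
    new1 <- sum(u1^2 * vals) / n1; new2 <- sum(u2^2 * vals) / n2
    if (max(abs(new1 - c1), abs(new2 - c2)) < tol) {
      c1 <- new1; c2 <- new2
      break
    }
    c1 <- new1; c2 <- new2
  }
  mean(c(c1, c2))
}

# pixel-loop CCFD% oracle
oracle_ccfd_percent <- function(fd, excluded, roi) {
  fd_n <- 0L; valid_n <- 0L
  for (r in seq_len(nrow(fd))) for (c in seq_len(ncol(fd))) {
    if (!roi[r, c] || excluded[r, c]) next
    valid_n <- valid_n + 1L
    if (fd[r, c]) fd_n <- fd_n + 1L
  }
  if (valid_n == 0L) NA_real_ else 100 * fd_n / valid_n
}

# voxel-loop slab projection oracle
oracle_slab_mean <- function(vol, bm, axial_um, offset_um, thickness_um) {
  h <- dim(vol)[1L]; w <- dim(vol)[2L]
  out <- matrix(NA_real_, h, w)
  lo <- ceiling(offset_um / axial_um)
  hi <- ceiling((offset_um + thickness_um) / axial_um) - 1L
  for (r in seq_len(h)) for (c in seq_len(w)) {
    ks <- (bm[r, c] + lo):(bm[r, c] + hi)
    out[r, c] <- mean(vol[r, c, ks + 1L])
  }
  out
}

small_measurement_table <- function(n_eyes = 12L, reps = 3L, sigma_eye = 2,
                                    sigma_res = 1, mean_ccfd = 9, seed = 5L) {
  set.seed(seed)
  eyes <- sprintf("e%02d", seq_len(n_eyes))
  data.frame(
    eye_id = rep(eyes, each = reps),
    repeat_index = rep(seq_len(reps), n_eyes),
    ccfd_percent = rep(stats::rnorm(n_eyes, mean_ccfd, sigma_eye), each = reps) +
      stats::rnorm(n_eyes * reps, 0, sigma_res),
    stringsAsFactors = FALSE
  )
}
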