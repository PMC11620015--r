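test_that("variance components: closed-form MoM handles degenerate and textbook cases", {
  # zero within-eye spread -> zero residual
  tab0 <- data.frame(eye_id = rep(c("a", "b", "c"), each = 3),
                     ccfd_percent = rep(c(5, 8, 11), each = 3))
  vc0 <- fit_variance_components(tab0, "eye_id")
  expect_equal(vc0$sigma2[["residual"]], 0)
  expect_equal(compute_icc(vc0), 1)

  # all variance residual -> ICC 0
  set.seed(3)
  tabr <- data.frame(eye_id = rep(c("a", "b", "c", "d"), each = 50),
                     ccfd_percent = rep(c(9, 9, 9, 9), each = 50) +
                       rnorm(200))
  # between-eye MoM estimate can go negative here; it is clamped with a warning
  expect_warning(vcr <- fit_variance_components(tabr, "eye_id"), "clamped")
  expect_lt(compute_icc(vcr), 0.35)

  # sigma2_between = 4, sigma2_res = 1 -> ICC = 0.8 by definition
  vc <- structure(list(sigma2 = c(eye_id = 4, residual = 1), total = 5,
                       method = "anova_mom", levels_used = "eye_id",
                       n_obs = 90L),
                  class = "variance_components")
  expect_equal(compute_icc(vc), 0.8)
  expect_error(
    compute_icc(structure(list(sigma2 = c(eye_id = 0, residual = 0),
                               total = 0), class = "variance_components")),
    "no variance")
})

test_that("MoM and REML agree on balanced nested designs to 1e-6 relative", {
  set.seed(14)
  # one level: 30 eyes x 3 repeats
  tab <- small_measurement_table(30, 3, sigma_eye = 2, sigma_res = 1)
  vm <- fit_variance_components(tab, "eye_id", method = "anova_mom")
  vr <- fit_variance_components(tab, "eye_id", method = "reml")
  expect_equal(vr$sigma2, vm$sigma2, tolerance = 1e-6)

  # three nested levels: patients / eyes / boxes x repeats
  tab3 <- expand.grid(rep = 1:3, box_id = c("b1", "b2"), eye = 1:2,
                      patient_id = sprintf("p%02d", 1:10))
  tab3$eye_id <- paste0(tab3$patient_id, "_e", tab3$eye)
  set.seed(15)
  pe <- rnorm(10, 0, sqrt(3)); ee <- rnorm(20, 0, 1); be <- rnorm(40, 0, 0.7)
  tab3$ccfd_percent <- 9 +
    pe[as.integer(factor(tab3$patient_id))] +
    ee[as.integer(factor(tab3$eye_id))] +
    be[as.integer(factor(paste(tab3$eye_id, tab3$box_id)))] +
    rnorm(nrow(tab3), 0, 0.5)
  vm3 <- fit_variance_components(tab3, c("patient_id", "eye_id", "box_id"),
                                 method = "anova_mom")
  vr3 <- fit_variance_components(tab3, c("patient_id", "eye_id", "box_id"),
                                 method = "reml")
  expect_equal(vr3$sigma2, vm3$sigma2, tolerance = 1e-6)
})

test_that("REML matches lme4 on an unbalanced nested table", {
  skip_if_not_installed("lme4")
  set.seed(21)
  tab <- small_measurement_table(20, 3, sigma_eye = 2, sigma_res = 1)
  tab <- tab[-c(2, 7, 8, 30, 55), ]  # break the balance
  vr <- fit_variance_components(tab, "eye_id", method = "reml")
  fm <- lme4::lmer(ccfd_percent ~ 1 + (1 | eye_id), tab, REML = TRUE)
  ref <- as.data.frame(lme4::VarCorr(fm))$vcov
  expect_equal(unname(vr$sigma2), ref, tolerance = 1e-4)
})

test_that("variance-component estimates are unbiased on simulated repeat designs", {
  set.seed(31)
  n_rep <- 300L
  est <- matrix(NA_real_, n_rep, 2L)
  for (r in seq_len(n_rep)) {
    tab <- data.frame(
      eye_id = rep(sprintf("e%02d", 1:30), each = 3),
      ccfd_percent = rep(rnorm(30, 9, 2), each = 3) + rnorm(90, 0, 1))
    vc <- fit_variance_components(tab, "eye_id")
    est[r, ] <- vc$sigma2
  }
  expect_lt(abs(mean(est[, 1L]) - 4) / 4, 0.1)
  expect_lt(abs(mean(est[, 2L]) - 1) / 1, 0.1)
})

test_that("MDC95 is exactly sqrt(2) x 1.96 x residual SD and scales linearly", {
  expect_equal(compute_mdc95(0)$mdc95, 0)
  expect_equal(compute_mdc95(1)$mdc95, sqrt(2) * 1.96)
  for (s in c(0.3, 1.4178, 5)) {
    expect_equal(compute_mdc95(s)$mdc95, sqrt(2) * 1.96 * s)
    expect_equal(compute_mdc95(2 * s)$mdc95, 2 * compute_mdc95(s)$mdc95)
  }
  # the 3.93% box-level repeatability bound corresponds to residual SD 1.4178
  expect_equal(3.93 / (sqrt(2) * 1.96), 1.4178, tolerance = 1e-4)
  expect_equal(compute_mdc95(3.93 / (sqrt(2) * 1.96))$mdc95, 3.93)
  # invariant to shifting all measurements by a constant
  tab <- small_measurement_table(10, 3)
  m1 <- compute_mdc95(fit_variance_components(tab, "eye_id"))
  tab$ccfd_percent <- tab$ccfd_percent + 50
  m2 <- compute_mdc95(fit_variance_components(tab, "eye_id"))
  expect_equal(m1$mdc95, m2$mdc95, tolerance = 1e-9)
})

test_that("bootstrap ICC interval is seed-deterministic with sane limits", {
  tab <- small_measurement_table(20, 3, sigma_eye = 2, sigma_res = 1, seed = 8)
  vc <- fit_variance_components(tab, "eye_id")
  a <- bootstrap_icc_ci(vc, tab, n_boot = 300L, seed = 99L)
  b <- bootstrap_icc_ci(vc, tab, n_boot = 300L, seed = 99L)
  expect_identical(a[c("icc", "ci_low", "ci_high")],
                   b[c("icc", "ci_low", "ci_high")])
  expect_lte(a$ci_low, a$icc)
  expect_gte(a$ci_high, a$icc)
  # near-zero residual truth -> interval concentrates near 1
  tab1 <- small_measurement_table(20, 3, sigma_eye = 2, sigma_res = 0.001,
                                  seed = 9)
  vc1 <- fit_variance_components(tab1, "eye_id")
  c1 <- bootstrap_icc_ci(vc1, tab1, n_boot = 300L, seed = 1L)
  expect_gt(c1$ci_low, 0.99)
})

test_that("group contrasts: null cases, shift recovery and Tukey ordering", {
  mk <- function(shift, gname, n = 20, seed_off = 0) {
    data.frame(
      eye_id = sprintf("%s_e%02d", gname, rep(seq_len(n), each = 3)),
      group_label = gname,
      ccfd_percent = rep(rnorm(n, 8 + shift, 1), each = 3) +
        rnorm(3 * n, 0, 0.5))
  }
  # two copies of the same data -> estimate 0, p 1
  set.seed(41)
  g1 <- mk(0, "a")
  g2 <- g1; g2$group_label <- "b"; g2$eye_id <- sub("^a", "b", g2$eye_id)
  same <- compare_groups(rbind(g1, g2))
  expect_equal(same$estimate, 0)
  expect_equal(same$p_adj, 1, tolerance = 1e-6)
  expect_equal(same$df, 38)  # 40 eyes - 2 groups

  # +2 shift recovered inside its Tukey CI (estimate is ctl - dis = -2)
  set.seed(42)
  tab <- rbind(mk(0, "ctl", 30), mk(2, "dis", 30))
  cmp <- compare_groups(tab)
  expect_equal(cmp$group1, "ctl")
  expect_gte(-2, cmp$ci_low); expect_lte(-2, cmp$ci_high)
  expect_lt(cmp$p_adj, 0.001)
  # adjusted p >= unadjusted two-sample p on eye means
  em <- tapply(tab$ccfd_percent, tab$eye_id, mean)
  gl <- tapply(tab$group_label, tab$eye_id, `[`, 1L)
  p_raw <- t.test(em[gl == "ctl"], em[gl == "dis"], var.equal = TRUE)$p.value
  expect_gte(cmp$p_adj, p_raw)
  expect_error(compare_groups(mk(0, "only")), "2 groups")
})

test_that("Tukey critical value agrees with a Monte-Carlo studentized-range oracle", {
  k <- 3; df <- 200
  q_pkg <- qtukey(0.95, nmeans = k, df = df)
  set.seed(4242)
  n_mc <- 20000L
  stat <- replicate(n_mc, {
    m <- rnorm(k)
    s <- sqrt(rchisq(1, df) / df)
    (max(m) - min(m)) / s
  })
  q_mc <- quantile(stat, 0.95, names = FALSE)
  expect_lt(abs(q_pkg - q_mc) / q_mc, 0.02)
})

test_that("familywise adjusted p is uniform under eye-level label permutation", {
  set.seed(99)
  minp <- replicate(400, {
    eyes <- sprintf("e%02d", 1:30)
    grp <- setNames(sample(rep(c("a", "b", "c"), each = 10)), eyes)
    tt <- data.frame(eye_id = rep(eyes, each = 3),
                     ccfd_percent = rep(rnorm(30, 8, 1), each = 3) +
                       rnorm(90, 0, 0.5))
    tt$group_label <- grp[tt$eye_id]
    min(compare_groups(tt)$p_adj)
  })
  expect_gt(stats::ks.test(minp, "punif")$p.value, 0.01)
})

test_that("change assessment applies the strict MDC95 rule with target/control roles", {
  mk_tab <- function(vals) {
    data.frame(roi_type = "box",
               roi_id = sprintf("box_%+d%+d", seq_along(vals) - 2L, 0L),
               ccfd_percent = vals, stringsAsFactors = FALSE)
  }
  base <- mk_tab(c(10, 30, 12))
  fu <- mk_tab(c(10, 20.44, 13))  # deltas: 0, -9.56, +1
  res <- assess_change(base, fu, mdc95_ref = 3.93, target_box_id = "box_+0+0")
  res <- res[order(res$roi_id), ]
  expect_equal(res$delta_ccfd[res$roi_id == "box_-1+0"], 0)
  expect_false(res$significant[res$roi_id == "box_-1+0"])
  expect_true(res$significant[res$roi_id == "box_+0+0"])   # -9.56
  expect_equal(res$role[res$roi_id == "box_+0+0"], "target")
  expect_equal(sort(unique(res$role)), c("control", "target"))
  # a change exactly equal to the MDC95 is not significant (strict rule)
  eq <- assess_change(mk_tab(c(12, 12, 12)), mk_tab(c(16, 12, 7)),
                      mdc95_ref = 4)
  eq <- eq[order(eq$roi_id), ]
  expect_false(eq$significant[eq$roi_id == "box_-1+0"])  # delta exactly +4
  expect_true(eq$significant[eq$roi_id == "box_+1+0"])   # delta -5
  # boxes present in only one visit are excluded with a warning
  fu2 <- fu[-1L, ]
  expect_warning(r2 <- assess_change(base, fu2, 3.93), "only one visit")
  expect_equal(nrow(r2), 2L)
})
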