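#' Pairwise group contrasts with Tukey adjustment
#'
#' Estimates mean CCFD% differences between study groups (e.g. normal,
#' iAMD, hyperTD) for one ROI by adding a group fixed effect to the
#' nested random-intercept model, then forms all pairwise contrasts with
#' Tukey's studentized-range adjustment. The studentized-range degrees
#' of freedom are `n_eyes - n_groups`; confidence intervals are at the
#' Tukey-adjusted level.
#'
#' For balanced one-random-level designs (equal repeats per eye, equal
#' eyes per group) the generalized-least-squares fit reduces exactly to
#' a one-way analysis of the per-eye means, which is used as a closed
#' form; otherwise the in-package REML fit is used.
#'
#' @param table Measurement table with the response, a group column and
#'   the grouping columns in `levels`.
#' @param levels Nesting columns, outermost first; the innermost is the
#'   unit (eye) whose count sets the degrees of freedom.
#' @param group_col Name of the group column (default `"group_label"`).
#' @param response Response column (default `"ccfd_percent"`).
#' @param conf_level Confidence level (default 0.95).
#' @return A data frame of class `group_comparisons`, one row per pair:
#'   `group1`, `group2`, `estimate` (group1 - group2), `ci_low`,
#'   `ci_high`, `p_adj`, `df`.
#' @export
compare_groups <- function(table, levels = "eye_id", group_col = "group_label",
                           response = "ccfd_percent", conf_level = 0.95) {
  stopifnot(group_col %in% names(table), all(levels %in% names(table)))
  y <- table[[response]]
  keep <- is.finite(y)
  if (any(!keep)) {
    message(sprintf("dropping %d row(s) with missing CCFD%%", sum(!keep)))
    table <- table[keep, , drop = FALSE]
    y <- table[[response]]
  }
  grp <- factor(table[[group_col]])
  k <- nlevels(grp)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  eye <- interaction(table[, levels, drop = FALSE], drop = TRUE)
  eyes_per_group <- tapply(as.character(eye), grp, function(e) length(unique(e)))
  if (any(eyes_per_group < 2L)) stop("each group needs >= 2 eyes", call. = FALSE)
  df <- length(unique(eye)) - k

  groups <- nested_groups(table, levels)
  balanced <- is_balanced_nested(groups) && length(levels) == 1L &&
    length(unique(eyes_per_group)) == 1L
  if (balanced) {
    # per-eye means: iid across eyes with variance sigma2_eye + sigma2_res/r
    em <- tapply(y, eye, mean)
    eg <- tapply(as.character(grp), eye, function(g) g[1L])
    gm <- tapply(em, eg, mean)
    mse <- sum(tapply(em, eg, function(v) sum((v - mean(v))^2))) / df
    n_per <- unique(eyes_per_group)
    est <- outer(gm, gm, `-`)
    se_d <- sqrt(2 * mse / n_per)
    se_mat <- matrix(se_d, k, k, dimnames = list(levels(grp), levels(grp)))
  } else {
    X <- stats::model.matrix(~ grp)
    fit <- reml_nested(y, X, groups)
    # cell means and their covariance
    L <- cbind(1, rbind(0, diag(k - 1L)))  # mean of each group from coefs
    mu <- as.numeric(L %*% fit$beta)
    Vmu <- L %*% fit$beta_vcov %*% t(L)
    gm <- stats::setNames(mu, levels(grp))
    est <- outer(gm, gm, `-`)
    se_mat <- sqrt(outer(diag(Vmu), diag(Vmu), `+`) - 2 * Vmu)
    dimnames(se_mat) <- list(levels(grp), levels(grp))
  }
  pairs <- utils::combn(levels(grp), 2L)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
    d <- est[g1, g2]
    se <- se_mat[g1, g2]
    qstat <- sqrt(2) * abs(d) / se
    p_adj <- 1 - stats::ptukey(qstat, nmeans = k, df = df)
    hw <- stats::qtukey(conf_level, nmeans = k, df = df) / sqrt(2) * se
    data.frame(group1 = g1, group2 = g2, estimate = d,
               ci_low = d - hw, ci_high = d + hw, p_adj = p_adj, df = df,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("group_comparisons", class(out))
  out
}

#' MDC95-based longitudinal change assessment
#'
#' Compares per-box CCFD% between a baseline and a follow-up visit on the
#' same grid. A box change is significant when its absolute delta
#' strictly exceeds the MDC95 reference (a change equal to the MDC95 is
#' not significant). The box containing the lesion of interest is the
#' target; all other boxes serve as internal controls.
#'
#' @param baseline,followup Measurement tables from
#'   [measure_visit_set()] (rows with `roi_type == "box"` are used; when
#'   a visit has several repeats, boxes are averaged across repeats).
#' @param mdc95_ref MDC95 reference value in CCFD percentage points
#'   (e.g. the 3.93 box-level repeatability bound).
#' @param target_box_id `roi_id` of the target box (default the grid
#'   centre box `"box_+0+0"`).
#' @return A data frame of class `change_assessment`: `roi_id`,
#'   `ccfd_baseline`, `ccfd_followup`, `delta_ccfd`
#'   (follow-up - baseline), `mdc95_ref`, `significant`, `role`.
#' @export
assess_change <- function(baseline, followup, mdc95_ref,
                          target_box_id = "box_+0+0") {
  pick <- function(tab) {
    b <- tab[tab$roi_type == "box" & is.finite(tab$ccfd_percent), , drop = FALSE]
    stats::aggregate(ccfd_percent ~ roi_id, data = b, FUN = mean)
  }
  b0 <- pick(baseline); b1 <- pick(followup)
  common <- intersect(b0$roi_id, b1$roi_id)
  missing <- union(setdiff(b0$roi_id, common), setdiff(b1$roi_id, common))
  if (length(missing)) {
    warning(sprintf("excluding %d box(es) present in only one visit: %s",
                    length(missing), paste(missing, collapse = ", ")),
            call. = FALSE)
  }
  m0 <- b0$ccfd_percent[match(common, b0$roi_id)]
  m1 <- b1$ccfd_percent[match(common, b1$roi_id)]
  out <- data.frame(
    roi_id = common,
    ccfd_baseline = m0,
    ccfd_followup = m1,
    delta_ccfd = m1 - m0,
    mdc95_ref = mdc95_ref,
    significant = abs(m1 - m0) > mdc95_ref,
    role = ifelse(common == target_box_id, "target", "control"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("change_assessment", class(out))
  out
}
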