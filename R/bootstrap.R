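#' Parametric bootstrap confidence interval for the ICC
#'
#' Simulates measurement tables from the fitted normal variance
#' components under the same nested design, refits each, and returns a
#' percentile confidence interval of the ICC. Deterministic given
#' `seed`. Refits use the closed-form method of moments, which matches
#' REML on the balanced designs the repeatability protocol produces.
#'
#' @param vc A [fit_variance_components()] result.
#' @param design The measurement table (or any data frame carrying the
#'   grouping columns in `vc$levels_used`, one row per observation).
#' @param n_boot Number of bootstrap samples (>= 100; default 1000, with
#'   larger counts such as the 100,000 used for publication-grade
#'   intervals available at the cost of runtime).
#' @param seed Integer RNG seed.
#' @param level Confidence level (default 0.95).
#' @return An object of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `n_boot`, `seed`, `n_failed` (refits dropped).
#' @export
bootstrap_icc_ci <- function(vc, design, n_boot = 1000L, seed = 1L,
                             level = 0.95) {
  stopifnot(n_boot >= 100L)
  levels <- vc$levels_used
  groups <- nested_groups(design, levels)
  icc_hat <- compute_icc(vc)
  sig <- vc$sigma2
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  q <- length(levels)
  n <- length(groups[[q]])
  idx <- lapply(groups, as.integer)
  nlev <- vapply(groups, nlevels, integer(1L))
  iccs <- rep(NA_real_, n_boot)
  balanced <- is_balanced_nested(groups)
  for (b in seq_len(n_boot)) {
    y <- stats::rnorm(n, sd = sqrt(sig[["residual"]]))
    for (l in seq_len(q)) {
      eff <- stats::rnorm(nlev[l], sd = sqrt(sig[[l]]))
      y <- y + eff[idx[[l]]]
    }
    # boundary clamping is routine in resampled refits; no per-sample warning
    fit <- tryCatch(
      suppressWarnings(
        if (balanced) mom_nested(y, groups)
        else reml_nested(y, matrix(1, n, 1L), groups)),
      error = function(e) NULL)
    if (is.null(fit)) next
    tot <- sum(fit$sigma2_levels) + fit$sigma2_res
    if (tot > 0) iccs[b] <- min(max(sum(fit$sigma2_levels) / tot, 0), 1)
  }
  n_failed <- sum(is.na(iccs))
  if (n_failed > 0.05 * n_boot) {
    warning(sprintf("%d of %d bootstrap refits failed", n_failed, n_boot),
            call. = FALSE)
  }
  alpha <- (1 - level) / 2
  ci <- stats::quantile(iccs, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  structure(list(icc = icc_hat, ci_low = ci[1L], ci_high = ci[2L],
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 n_failed = as.integer(n_failed)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC %.3f (95%% CI %.3f-%.3f; %d bootstrap samples)\n",
              x$icc, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}
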