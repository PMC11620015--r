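#' Fit a nested variance-components model
#'
#' Unconditional linear mixed model with nested random intercepts
#' (e.g. patients, eyes within patients, grid boxes within eyes) and a
#' residual that captures repeat-to-repeat variation of the same ROI at
#' the same visit. Balanced tables are fitted by expected-mean-squares
#' method of moments (`"anova_mom"`, closed form); unbalanced tables by
#' REML (profiled likelihood over variance ratios, derivative-free
#' optimisation, components clamped at zero).
#'
#' @param table Data frame with a `ccfd_percent` response column and one
#'   column per nesting level; rows with `NA` response are dropped with a
#'   message.
#' @param levels Character vector of grouping column names, outermost
#'   first (e.g. `c("patient_id", "eye_id", "roi_id")`); the residual
#'   level is the repeat.
#' @param method `"auto"` (MoM when balanced, REML otherwise),
#'   `"anova_mom"` or `"reml"`.
#' @param response Response column name (default `"ccfd_percent"`).
#' @return An object of class `variance_components`: `sigma2` (named
#'   vector, one per level plus `"residual"`), `total`, `method`,
#'   `loglik` (REML criterion, `NA` for MoM), `levels_used`, `n_obs`.
#' @export
fit_variance_components <- function(table, levels, method = c("auto", "anova_mom", "reml"),
                                    response = "ccfd_percent") {
  method <- match.arg(method)
  stopifnot(all(levels %in% names(table)), response %in% names(table))
  y <- table[[response]]
  drop <- !is.finite(y)
  if (any(drop)) {
    message(sprintf("dropping %d row(s) with missing CCFD%%", sum(drop)))
    table <- table[!drop, , drop = FALSE]
    y <- table[[response]]
  }
  groups <- nested_groups(table, levels)
  innermost <- groups[[length(groups)]]
  reps <- table(innermost)
  if (!any(reps >= 2L) || sum(reps >= 2L) < 2L) {
    stop("need >= 2 repeats for >= 2 units at the residual level", call. = FALSE)
  }
  balanced <- is_balanced_nested(groups)
  if (method == "auto") method <- if (balanced) "anova_mom" else "reml"
  if (method == "anova_mom" && !balanced) {
    stop("anova_mom requires a balanced nested table; use method = 'reml'",
         call. = FALSE)
  }
  fit <- if (method == "anova_mom") {
    mom_nested(y, groups)
  } else {
    reml_nested(y, X = matrix(1, length(y), 1L), groups = groups)
  }
  sigma2 <- c(fit$sigma2_levels, residual = fit$sigma2_res)
  names(sigma2) <- c(levels, "residual")
  structure(list(sigma2 = sigma2, total = sum(sigma2), method = method,
                 loglik = fit$loglik, levels_used = levels,
                 n_obs = length(y)),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> (%s, n=%d)\n", x$method, x$n_obs))
  for (nm in names(x$sigma2)) {
    cat(sprintf("  sigma2[%s] = %.6g (%.1f%%)\n", nm, x$sigma2[[nm]],
                100 * x$sigma2[[nm]] / x$total))
  }
  invisible(x)
}

# list of nested grouping factors, outermost first; level l groups are
# the interaction of columns 1..l so nesting is enforced
nested_groups <- function(table, levels) {
  acc <- NULL
  out <- vector("list", length(levels))
  for (l in seq_along(levels)) {
    acc <- if (is.null(acc)) as.character(table[[levels[l]]])
           else paste(acc, table[[levels[l]]], sep = "\r")
    out[[l]] <- factor(acc)
  }
  out
}

is_balanced_nested <- function(groups) {
  # equal replicates within every group at every level, and equal numbers
  # of subgroups within each parent
  for (l in seq_along(groups)) {
    if (length(unique(table(groups[[l]]))) != 1L) return(FALSE)
    if (l > 1L) {
      sub_per_parent <- tapply(groups[[l]], groups[[l - 1L]],
                               function(g) length(unique(g)))
      if (length(unique(sub_per_parent)) != 1L) return(FALSE)
    }
  }
  TRUE
}

# Expected-mean-squares estimators for the balanced fully nested design.
mom_nested <- function(y, groups) {
  q <- length(groups)
  n <- length(y)
  grand <- mean(y)
  means <- vector("list", q)
  for (l in seq_len(q)) means[[l]] <- ave(y, groups[[l]])
  ss <- numeric(q + 1L); df <- numeric(q + 1L)
  for (l in seq_len(q)) {
    upper <- if (l == 1L) rep(grand, n) else means[[l - 1L]]
    ss[l] <- sum((means[[l]] - upper)^2)
    df[l] <- nlevels(groups[[l]]) - (if (l == 1L) 1L else nlevels(groups[[l - 1L]]))
  }
  ss[q + 1L] <- sum((y - means[[q]])^2)
  df[q + 1L] <- n - nlevels(groups[[q]])
  ms <- ss / df
  N_per <- vapply(groups, function(g) n / nlevels(g), numeric(1L))  # obs per group
  sigma2 <- numeric(q)
  for (l in q:1) {
    upper_ms <- if (l == q) ms[q + 1L] else ms[l + 1L]
    sigma2[l] <- (ms[l] - upper_ms) / N_per[l]
  }
  if (any(sigma2 < 0)) {
    warning("negative method-of-moments variance estimate clamped to 0",
            call. = FALSE)
    sigma2[sigma2 < 0] <- 0
  }
  list(sigma2_levels = sigma2, sigma2_res = ms[q + 1L], loglik = NA_real_)
}

# REML for nested random intercepts, profiled over variance ratios
# theta_l = sigma2_l / sigma2_res, computed block-wise by outermost group.
# X is the fixed-effects design (intercept, or group dummies).
reml_nested <- function(y, X, groups, tol = 1e-8) {
  q <- length(groups)
  n <- length(y)
  p <- qr(X)$rank
  blocks <- split(seq_len(n), groups[[1L]])
  # per-block random-intercept index lists (level 1 = whole block)
  zidx <- lapply(blocks, function(ix) {
    lapply(seq_len(q), function(l) as.integer(factor(as.character(groups[[l]][ix]))))
  })
  crit <- function(log_theta) {
    theta <- exp(log_theta)
    logdet_w <- 0
    xtwx <- matrix(0, ncol(X), ncol(X))
    xtwy <- numeric(ncol(X))
    winv_list <- vector("list", length(blocks))
    for (b in seq_along(blocks)) {
      ix <- blocks[[b]]
      nb <- length(ix)
      W <- diag(nb)
      for (l in seq_len(q)) {
        zl <- zidx[[b]][[l]]
        Zl <- outer(zl, seq_len(max(zl)), `==`) * 1
        W <- W + theta[l] * tcrossprod(Zl)
      }
      ch <- chol(W)
      logdet_w <- logdet_w + 2 * sum(log(diag(ch)))
      Winv <- chol2inv(ch)
      winv_list[[b]] <- Winv
      Xb <- X[ix, , drop = FALSE]
      xtwx <- xtwx + crossprod(Xb, Winv %*% Xb)
      xtwy <- xtwy + crossprod(Xb, Winv %*% y[ix])
    }
    beta <- solve(xtwx, xtwy)
    rss <- 0
    for (b in seq_along(blocks)) {
      ix <- blocks[[b]]
      r <- y[ix] - X[ix, , drop = FALSE] %*% beta
      rss <- rss + crossprod(r, winv_list[[b]] %*% r)[1L, 1L]
    }
    sigma2 <- rss / (n - p)
    val <- 0.5 * (logdet_w + (n - p) * log(sigma2) +
                    determinant(xtwx, logarithm = TRUE)$modulus[1L])
    attr(val, "sigma2") <- sigma2
    attr(val, "beta") <- beta
    attr(val, "xtwx") <- xtwx
    val
  }
  # start from MoM when available, else equal split
  start <- tryCatch({
    if (is_balanced_nested(groups) && ncol(X) == 1L) {
      m <- mom_nested(y, groups)
      pmax(m$sigma2_levels, 1e-4) / max(m$sigma2_res, 1e-8)
    } else rep(1, q)
  }, error = function(e) rep(1, q))
  lt0 <- log(pmax(start, 1e-6))
  if (q == 1L) {
    opt <- stats::optimize(function(l) as.numeric(crit(l)),
                           interval = c(-30, 30), tol = tol)
    lt <- opt$minimum
    # boundary check: effectively-zero ratio
    if (as.numeric(crit(-30)) <= opt$objective + tol) lt <- -30
  } else {
    opt <- stats::optim(lt0, function(l) as.numeric(crit(l)),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 5000))
    lt <- opt$par
  }
  final <- crit(lt)
  sigma2_res <- attr(final, "sigma2")
  theta <- exp(lt)
  sigma2_levels <- theta * sigma2_res
  sigma2_levels[theta < 1e-8] <- 0  # clamped at the boundary
  list(sigma2_levels = sigma2_levels, sigma2_res = sigma2_res,
       loglik = -as.numeric(final),
       beta = attr(final, "beta"),
       beta_vcov = sigma2_res * solve(attr(final, "xtwx")))
}

#' Intraclass correlation coefficient
#'
#' ICC is the ratio of the total variance less the residual variance
#' (the variance due to repeated scans) to the total variance, clipped
#' to `[0, 1]`.
#'
#' @param vc A [fit_variance_components()] result.
#' @return ICC in `[0, 1]`.
#' @export
compute_icc <- function(vc) {
  total <- vc$total
  if (total <= 0) stop("no variance: total variance is zero", call. = FALSE)
  min(max((total - vc$sigma2[["residual"]]) / total, 0), 1)
}

#' 95% minimal detectable change
#'
#' `MDC95 = sqrt(2) * 1.96 * residual SD`, the smallest between-visit
#' change in CCFD% that exceeds test-retest measurement variability with
#' 95% confidence.
#'
#' @param vc A [fit_variance_components()] result, or a bare residual SD.
#' @return An object of class `mdc_result` with `residual_sd` and
#'   `mdc95`.
#' @export
compute_mdc95 <- function(vc) {
  residual_sd <- if (inherits(vc, "variance_components")) {
    sqrt(vc$sigma2[["residual"]])
  } else {
    as.numeric(vc)
  }
  stopifnot(residual_sd >= 0)
  structure(list(residual_sd = residual_sd,
                 mdc95 = sqrt(2) * 1.96 * residual_sd),
            class = "mdc_result")
}

#' @export
print.mdc_result <- function(x, ...) {
  cat(sprintf("<mdc_result> residual SD %.4g -> MDC95 %.4g\n",
              x$residual_sd, x$mdc95))
  invisible(x)
}
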