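#' Standardized major axis line fit
#'
#' Fits the SMA (reduced major axis) line to one group:
#' `b = sign(s_xy) * sqrt(s_yy / s_xx)`, `a = ybar - b * xbar`. The slope
#' confidence interval is the standard F-based interval driven by
#' `(1 - r^2)`. SMA is the appropriate line when both variables carry
#' biological/measurement variation, as for two log body-part sizes.
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-zero variance.
#' @param alpha confidence level for the slope CI is `1 - alpha`.
#' @return an object of class `"sma_fit"`: `slope`, `elevation`, `n`, `r`,
#'   `slope_ci`, `minimal_n` (flag for n = 3).
#' @examples
#' f <- sma_fit(c(0, 1, 2), c(0, 2, 3))
#' f$slope # sqrt(7/3)
#' @export
sma_fit <- function(x, y, alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("sma_fit needs at least 3 complete observations",
                   call. = FALSE)
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxx <= 0 || syy <= 0) stop("zero variance in x or y", call. = FALSE)
  sgn <- sign(sxy)
  if (sgn == 0) {
    warning("zero covariance between x and y; SMA slope sign set positive")
    sgn <- 1
  }
  b <- sgn * sqrt(syy / sxx)
  a <- mean(y) - b * mean(x)
  r <- sxy / sqrt(sxx * syy)
  B <- stats::qf(1 - alpha, 1, n - 2) * max(1 - r^2, 0) / (n - 2)
  ci <- sort(b * (sqrt(B + 1) + c(-1, 1) * sqrt(B)))
  structure(list(slope = b, elevation = a, n = n, r = r,
                 slope_ci = ci, alpha = alpha, minimal_n = n == 3L,
                 xbar = mean(x), ybar = mean(y),
                 sxx = sxx, syy = syy, sxy = sxy),
            class = "sma_fit")
}

#' @export
print.sma_fit <- function(x, ...) {
  cat(sprintf("SMA fit (n = %d%s): slope = %.4f [%.4f, %.4f], elevation = %.4f, r = %.3f\n",
              x$n, if (x$minimal_n) ", minimal-n" else "",
              x$slope, x$slope_ci[1], x$slope_ci[2], x$elevation, x$r))
  invisible(x)
}

# ---- grouped SMA internals -------------------------------------------------
# Per-group sufficient statistics; all multi-group inference works off these.
sma_group_stats <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  list(n = length(x), xbar = mean(x), ybar = mean(y),
       sxx = stats::var(x), syy = stats::var(y), sxy = stats::cov(x, y))
}

# "residual" and "fitted-axis" variances of the SMA likelihood at slope b;
# clamped away from zero so exactly collinear data stay finite
sma_rf <- function(st, b) {
  scale <- st$syy + b^2 * st$sxx
  r <- max(st$syy - 2 * b * st$sxy + b^2 * st$sxx, 1e-14 * scale)
  f <- max(st$syy + 2 * b * st$sxy + b^2 * st$sxx, 1e-14 * scale)
  c(r = r, f = f)
}

# profile -2 log-likelihood contribution of one group at slope b (up to a
# b-free constant): w * log(r(b) f(b) / b^2). The b^-2 term is the Jacobian
# of the rotation to residual/fitted axes.
sma_q <- function(stats_list, b, w) {
  sum(vapply(seq_along(stats_list), function(i) {
    rf <- sma_rf(stats_list[[i]], b)
    w[i] * (log(rf["r"]) + log(rf["f"]) - 2 * log(abs(b)))
  }, numeric(1)))
}

# common-slope estimate: minimize the summed profile on the log-|b| scale,
# searching around the spread of the per-group SMA slopes
sma_common_slope <- function(stats_list, w, tol = 1e-8) {
  bs <- vapply(stats_list, function(st) {
    s <- sign(st$sxy); if (s == 0) s <- 1
    s * sqrt(st$syy / st$sxx)
  }, numeric(1))
  sgn <- sign(sum(vapply(stats_list, function(st) st$n * st$sxy, numeric(1))))
  if (sgn == 0) sgn <- 1
  lo <- log(min(abs(bs)) / 20); hi <- log(max(abs(bs)) * 20)
  opt <- stats::optimize(function(t) sma_q(stats_list, sgn * exp(t), w),
                         interval = c(lo, hi), tol = tol)
  sgn * exp(opt$minimum)
}

# sampling variance of the common slope from the observed information of the
# profile likelihood (weights = per-group residual dfs)
sma_slope_var <- function(stats_list, b, w) {
  h <- function(bb) 0.5 * sma_q(stats_list, bb, w)
  eps <- 1e-4 * abs(b)
  info <- (h(b + eps) - 2 * h(b) + h(b - eps)) / eps^2
  if (!is.finite(info) || info <= 0) return(NA_real_)
  1 / info
}

#' Common-slope test for grouped SMA lines
#'
#' Estimates the slope shared by several groups by maximizing the grouped SMA
#' profile likelihood, and tests slope homogeneity with the likelihood-ratio
#' statistic against chi-square on g - 1 df. Per-group weights use the
#' residual degrees of freedom (n_i - 2), which keeps the null distribution
#' close to chi-square at the moderate sample sizes typical of intraspecific
#' allometry.
#'
#' @param groups a list with one element per group, each a list/data.frame
#'   with components `x` and `y`.
#' @return list: `b_common`, `statistic`, `df`, `p_value`, `slopes`
#'   (per-group SMA slopes), `var_b` (sampling variance of `b_common`).
#' @export
common_slope_test <- function(groups) {
  stats_list <- lapply(groups, function(g) sma_group_stats(g$x, g$y))
  ns <- vapply(stats_list, `[[`, numeric(1), "n")
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(ns < 3)) stop("every group needs n >= 3", call. = FALSE)
  w <- ns - 2
  b_c <- sma_common_slope(stats_list, w)
  q_common <- sma_q(stats_list, b_c, w)
  q_sep <- sum(vapply(seq_along(stats_list), function(i) {
    st <- stats_list[[i]]
    s <- sign(st$sxy); if (s == 0) s <- 1
    bi <- s * sqrt(st$syy / st$sxx)
    rf <- sma_rf(st, bi)
    w[i] * (log(rf["r"]) + log(rf["f"]) - 2 * log(abs(bi)))
  }, numeric(1)))
  lr <- max(q_common - q_sep, 0)
  df <- length(groups) - 1L
  list(b_common = b_c, statistic = lr, df = df,
       p_value = stats::pchisq(lr, df, lower.tail = FALSE),
       slopes = vapply(stats_list, function(st) {
         s <- sign(st$sxy); if (s == 0) s <- 1
         s * sqrt(st$syy / st$sxx)
       }, numeric(1)),
       var_b = sma_slope_var(stats_list, b_c, w))
}

# elevations and their covariance matrix at a (shared) slope
sma_elevations <- function(stats_list, b, var_b) {
  g <- length(stats_list)
  a <- vapply(stats_list, function(st) st$ybar - b * st$xbar, numeric(1))
  xbars <- vapply(stats_list, `[[`, numeric(1), "xbar")
  ns <- vapply(stats_list, `[[`, numeric(1), "n")
  s2res <- vapply(stats_list, function(st) {
    rf <- sma_rf(st, b)
    unname(rf["r"]) * (st$n - 1) / (st$n - 2)
  }, numeric(1))
  if (!is.finite(var_b)) var_b <- 0
  V <- outer(xbars, xbars) * var_b
  diag(V) <- diag(V) + s2res / ns
  list(a = a, V = V)
}

#' Elevation (intercept) Wald test at a common slope
#'
#' Tests equality of group elevations `a_i = ybar_i - b_c * xbar_i` with a
#' Wald chi-square on g - 1 df. `var(a_i)` combines the residual variance at
#' the common slope with the uncertainty of the common slope itself
#' (`xbar_i^2 var(b_c)`), which also induces the covariance between group
#' elevations.
#'
#' @inheritParams common_slope_test
#' @param b_common optional common slope; estimated from `groups` if missing.
#' @return list: `W`, `df`, `p_value`, `elevations`, `b_common`, plus the
#'   elevation covariance matrix `V_a`.
#' @export
elevation_test <- function(groups, b_common = NULL) {
  stats_list <- lapply(groups, function(g) sma_group_stats(g$x, g$y))
  ns <- vapply(stats_list, `[[`, numeric(1), "n")
  if (any(ns < 3)) stop("every group needs n >= 3", call. = FALSE)
  w <- ns - 2
  if (is.null(b_common)) b_common <- sma_common_slope(stats_list, w)
  var_b <- sma_slope_var(stats_list, b_common, w)
  el <- sma_elevations(stats_list, b_common, var_b)
  Vi <- solve(el$V)
  one <- rep(1, length(el$a))
  W <- drop(el$a %*% Vi %*% el$a - (one %*% Vi %*% el$a)^2 / (one %*% Vi %*% one))
  W <- max(W, 0)
  df <- length(groups) - 1L
  list(W = W, df = df, p_value = stats::pchisq(W, df, lower.tail = FALSE),
       elevations = el$a, b_common = b_common, var_b = var_b, V_a = el$V)
}

#' Grouped SMA fit with common-slope and elevation inference
#'
#' The full multi-group SMA analysis: per-group [sma_fit()]s, the
#' common-slope likelihood-ratio test, and — at the common slope — the
#' elevation Wald test. This is the machinery used to ask whether species
#' share an intraspecific scaling slope while differing in elevation (grade
#' shifts).
#'
#' @param formula a two-sided formula `y ~ x` naming columns of `data`.
#' @param data a data frame or [trait_table()].
#' @param group grouping column name; defaults to the trait table's species
#'   column.
#' @param alpha significance level used for CIs and flags.
#' @return an object of class `"sma_group"`: `fits` (named list of
#'   `sma_fit`), `b_common`, `slope_test`, `elevation_test`, `groups`,
#'   `alpha`.
#' @seealso [pairwise_elevation()]
#' @export
sma_group <- function(formula, data, group = NULL, alpha = 0.05) {
  df <- as.data.frame(data)
  if (is.null(group)) group <- attr(data, "species_col") %||% "species"
  if (!group %in% names(df)) {
    stop("grouping column '", group, "' not found", call. = FALSE)
  }
  vars <- all.vars(formula)
  if (length(vars) != 2L) stop("formula must be y ~ x", call. = FALSE)
  yv <- df[[vars[1]]]; xv <- df[[vars[2]]]
  gl <- factor(df[[group]])
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]; gl <- droplevels(gl[keep])
  glist <- lapply(levels(gl), function(l) list(x = xv[gl == l], y = yv[gl == l]))
  names(glist) <- levels(gl)
  ns <- vapply(glist, function(g) length(g$x), numeric(1))
  if (any(ns < 3)) {
    stop("groups with n < 3: ", paste(names(glist)[ns < 3], collapse = ", "),
         call. = FALSE)
  }
  fits <- lapply(glist, function(g) sma_fit(g$x, g$y, alpha = alpha))
  st <- common_slope_test(glist)
  if (st$p_value < alpha) {
    warning("common slope rejected (p = ", signif(st$p_value, 3),
            "); elevation comparisons assume a shared slope")
  }
  et <- elevation_test(glist, b_common = st$b_common)
  structure(list(fits = fits, b_common = st$b_common,
                 slope_test = st[c("statistic", "df", "p_value", "slopes")],
                 elevation_test = et[c("W", "df", "p_value", "elevations")],
                 var_b = st$var_b, groups = glist, alpha = alpha,
                 formula = formula, group_col = group),
            class = "sma_group")
}

#' @export
print.sma_group <- function(x, ...) {
  cat("Grouped SMA:", deparse(x$formula), "|", length(x$fits), "groups\n")
  cat(sprintf("Common slope b = %.4f; slope LR = %.3f (df = %d, p = %.4g)\n",
              x$b_common, x$slope_test$statistic, x$slope_test$df,
              x$slope_test$p_value))
  cat(sprintf("Elevation Wald W = %.3f (df = %d, p = %.4g)\n",
              x$elevation_test$W, x$elevation_test$df,
              x$elevation_test$p_value))
  tab <- data.frame(
    n = vapply(x$fits, `[[`, numeric(1), "n"),
    slope = vapply(x$fits, `[[`, numeric(1), "slope"),
    elevation = vapply(x$fits, `[[`, numeric(1), "elevation"),
    r = vapply(x$fits, `[[`, numeric(1), "r"))
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.sma_group <- function(object, ...) {
  data.frame(group = names(object$fits),
             slope = vapply(object$fits, `[[`, numeric(1), "slope"),
             elevation_at_common_slope = object$elevation_test$elevations,
             row.names = NULL)
}

#' @export
plot.sma_group <- function(x, ...) {
  xv <- unlist(lapply(x$groups, `[[`, "x"))
  yv <- unlist(lapply(x$groups, `[[`, "y"))
  gl <- rep(seq_along(x$groups), vapply(x$groups, function(g) length(g$x),
                                        numeric(1)))
  graphics::plot(xv, yv, col = gl, pch = 16,
                 xlab = all.vars(x$formula)[2], ylab = all.vars(x$formula)[1],
                 ...)
  for (i in seq_along(x$groups)) {
    graphics::abline(x$elevation_test$elevations[i], x$b_common, col = i)
  }
  graphics::legend("topleft", legend = names(x$groups), col =
                     seq_along(x$groups), pch = 16, cex = 0.7, bty = "n")
  invisible(x)
}

#' Pairwise elevation-shift matrix
#'
#' For every unordered pair of groups, a df = 1 elevation Wald test together
#' with the signed elevation difference, arranged as matrices: the shift
#' matrix behind pairwise species comparisons of scaling elevations. By
#' default the slope is re-estimated per pair (`slope = "pairwise"`); with
#' `slope = "common"` all pairs reuse the globally estimated common slope.
#'
#' @param object an [sma_group()] fit.
#' @param slope `"pairwise"` (default) or `"common"`.
#' @param alpha significance level recorded in the result.
#' @return an object of class `"shift_matrix"`: `groups`, `delta` (g x g
#'   antisymmetric elevation differences, `a_i - a_j`), `W` (symmetric df = 1
#'   Wald statistics), `p`, `p_holm` (Holm-adjusted across the g(g-1)/2
#'   pairs), `slope_used`.
#' @export
pairwise_elevation <- function(object, slope = c("pairwise", "common"),
                               alpha = object$alpha %||% 0.05) {
  slope <- match.arg(slope)
  groups <- object$groups
  g <- length(groups)
  nm <- names(groups)
  delta <- W <- p <- matrix(0, g, g, dimnames = list(nm, nm))
  bmat <- matrix(NA_real_, g, g, dimnames = list(nm, nm))
  for (i in seq_len(g - 1)) {
    for (j in seq.int(i + 1, g)) {
      pair <- groups[c(i, j)]
      b_use <- if (slope == "pairwise") NULL else object$b_common
      et <- elevation_test(pair, b_common = b_use)
      d <- et$elevations[1] - et$elevations[2]
      delta[i, j] <- d; delta[j, i] <- -d
      W[i, j] <- W[j, i] <- et$W
      p[i, j] <- p[j, i] <- et$p_value
      bmat[i, j] <- bmat[j, i] <- et$b_common
    }
  }
  pu <- p[upper.tri(p)]
  ph <- stats::p.adjust(pu, method = "holm")
  p_holm <- matrix(0, g, g, dimnames = list(nm, nm))
  p_holm[upper.tri(p_holm)] <- ph
  p_holm <- p_holm + t(p_holm)
  structure(list(groups = nm, delta = delta, W = W, p = p, p_holm = p_holm,
                 pair_slopes = bmat, slope_used = slope, alpha = alpha),
            class = "shift_matrix")
}

#' @export
print.shift_matrix <- function(x, ...) {
  cat("Pairwise elevation shifts (", x$slope_used, " slope):\n", sep = "")
  cat("delta (a_i - a_j):\n"); print(round(x$delta, 4))
  cat("Wald p-values:\n"); print(signif(x$p, 3))
  invisible(x)
}

#' @export
as.data.frame.shift_matrix <- function(x, ...) {
  g <- length(x$groups)
  idx <- which(upper.tri(x$delta), arr.ind = TRUE)
  data.frame(
    group_i = x$groups[idx[, 1]], group_j = x$groups[idx[, 2]],
    delta_elevation = x$delta[idx], W = x$W[idx], p = x$p[idx],
    p_holm = x$p_holm[idx], row.names = NULL)
}
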