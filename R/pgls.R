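#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits the linear model `formula` by generalized least squares with error
#' covariance proportional to a lambda-transformed Brownian-motion matrix:
#' `V(lambda) = lambda * C` off the diagonal, `diag(C)` on it. With
#' `lambda = 0` the model collapses to ordinary least squares on a star
#' phylogeny; with `lambda = 1` it is pure Brownian motion. `lambda` can be
#' fixed or profiled out by maximum (restricted) likelihood with a
#' golden-section search on `[0, 1]`.
#'
#' Rows with missing values in any model variable are dropped for this fit
#' only, and the n actually used is reported. One row per species is
#' required.
#'
#' @param formula model formula, e.g. `log_esa ~ log_fsa + log_body`.
#' @param data a [trait_table()] or data frame; species labels are taken from
#'   the table's species column, the `species` argument, or row names.
#' @param tree a `"phylo"` object (used to build `C` when `cov` is missing).
#' @param cov a precomputed covariance matrix from [bm_covariance()].
#' @param lambda `"ML"` to estimate Pagel's lambda, or a fixed value in
#'   `[0, 1]`.
#' @param method `"REML"` (default; less biased residual variance at small n)
#'   or `"ML"` — the criterion used both for the reported log-likelihood and
#'   for profiling lambda.
#' @param species optional column name holding species labels.
#' @return an object of class `"pgls"` with components `coefficients`, `se`,
#'   `tstat`, `pval`, `df.residual`, `residuals` (ordinary, response units),
#'   `fitted.values`, `sigma2`, `lambda`, `logLik`, `n`, plus the design
#'   pieces needed by [anova_term()].
#' @seealso [bm_covariance()], [lambda_transform()], [anova_term()],
#'   [slope_test()]
#' @examples
#' tr <- simulate_tree(30, seed = 1)
#' tt <- simulate_species_traits(tr, sim_config(seed = 1))
#' fit <- pgls(esa ~ body, data = tt, tree = tr)
#' summary(fit)
#' @export
pgls <- function(formula, data, tree = NULL, cov = NULL, lambda = "ML",
                 method = c("REML", "ML"), species = NULL) {
  method <- match.arg(method)
  if (is.null(cov)) {
    if (is.null(tree)) stop("supply either 'tree' or 'cov'", call. = FALSE)
    cov <- bm_covariance(tree)
  }
  data <- as.data.frame(data)
  sp <- pgls_species_labels(data, species)

  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  used <- attr(mf, "na.action")
  keep <- if (is.null(used)) seq_len(nrow(data)) else setdiff(seq_len(nrow(data)), used)
  sp <- sp[keep]
  if (anyDuplicated(sp)) {
    stop("pgls needs one row per species; duplicated: ",
         paste(unique(sp[duplicated(sp)]), collapse = ", "), call. = FALSE)
  }
  missing_sp <- setdiff(sp, rownames(cov))
  if (length(missing_sp)) {
    stop("species absent from covariance matrix: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  C <- cov[sp, sp, drop = FALSE]

  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y)
  p <- ncol(X)
  if (n < p + 1L) stop("too few usable rows (", n, ") for ", p,
                       " parameters", call. = FALSE)
  if (qr(X)$rank < p) {
    stop("rank-deficient design; collinear columns among: ",
         paste(colnames(X), collapse = ", "), call. = FALSE)
  }

  if (identical(lambda, "ML") || identical(lambda, "ml")) {
    opt <- stats::optimize(function(l) pgls_loglik(lambda_transform(C, l),
                                                   X, y, method),
                           interval = c(0, 1), maximum = TRUE, tol = 1e-6)
    lam <- opt$maximum
    # optimize() cannot return an exact boundary; snap when a boundary is
    # at least as good, so lambda = 0 / 1 data report boundary estimates
    for (b in c(0, 1)) {
      if (pgls_loglik(lambda_transform(C, b), X, y, method) >= opt$objective) {
        lam <- b
      }
    }
    lambda_estimated <- TRUE
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
      stop("lambda must be 'ML' or a value in [0, 1]", call. = FALSE)
    }
    lam <- lambda
    lambda_estimated <- FALSE
  }

  V <- lambda_transform(C, lam)
  U <- tryCatch(chol(V), error = function(e)
    stop("singular phylogenetic covariance (lambda = ", lam, ")",
         call. = FALSE))
  ys <- backsolve(U, y, transpose = TRUE)
  Xs <- backsolve(U, X, transpose = TRUE)
  qrX <- qr(Xs)
  beta <- stats::setNames(qr.coef(qrX, ys), colnames(X))
  rss <- sum(qr.resid(qrX, ys)^2)
  df_res <- n - p
  sigma2 <- rss / df_res
  XtViX_inv <- chol2inv(qr.R(qrX))
  vc <- sigma2 * XtViX_inv
  dimnames(vc) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vc))
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), df_res)
  fitted <- drop(X %*% beta)

  out <- list(
    coefficients = beta, se = se, tstat = tstat, pval = pval,
    df.residual = df_res, residuals = stats::setNames(y - fitted, sp),
    fitted.values = stats::setNames(fitted, sp),
    sigma2 = sigma2, lambda = lam, lambda_estimated = lambda_estimated,
    logLik = pgls_loglik(V, X, y, method), method = method,
    n = n, p = p, species = sp, y = y, X = X, C = C, V = V,
    vcov = vc, formula = formula, call = match.call()
  )
  class(out) <- "pgls"
  out
}

pgls_species_labels <- function(data, species) {
  if (!is.null(species)) {
    if (!species %in% names(data)) {
      stop("species column '", species, "' not found", call. = FALSE)
    }
    return(as.character(data[[species]]))
  }
  sc <- attr(data, "species_col")
  if (!is.null(sc) && sc %in% names(data)) return(as.character(data[[sc]]))
  if ("species" %in% names(data)) return(as.character(data$species))
  rownames(data)
}

# profile log-likelihood of the GLS model at covariance V (sigma^2 profiled)
pgls_loglik <- function(V, X, y, method) {
  n <- length(y)
  p <- ncol(X)
  U <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(U)) return(-Inf)
  logdetV <- 2 * sum(log(diag(U)))
  ys <- backsolve(U, y, transpose = TRUE)
  Xs <- backsolve(U, X, transpose = TRUE)
  qrX <- qr(Xs)
  rss <- sum(qr.resid(qrX, ys)^2)
  if (method == "ML") {
    s2 <- rss / n
    -0.5 * (n * log(2 * pi * s2) + logdetV + n)
  } else {
    s2 <- rss / (n - p)
    logdetXtViX <- 2 * sum(log(abs(diag(qr.R(qrX)))))
    -0.5 * ((n - p) * log(2 * pi * s2) + logdetV + logdetXtViX + (n - p))
  }
}

#' @export
print.pgls <- function(x, ...) {
  cat("Phylogenetic GLS (Pagel's lambda)\n")
  cat("  formula:", deparse(x$formula), "\n")
  cat(sprintf("  lambda = %.4f%s, %s log-likelihood = %.3f, n = %d\n",
              x$lambda, if (x$lambda_estimated) " (ML)" else " (fixed)",
              x$method, x$logLik, x$n))
  cat("Coefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.pgls <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$tstat, `Pr(>|t|)` = object$pval)
  out <- list(coefficients = tab, lambda = object$lambda,
              lambda_estimated = object$lambda_estimated,
              sigma2 = object$sigma2, df.residual = object$df.residual,
              logLik = object$logLik, method = object$method,
              n = object$n, formula = object$formula)
  class(out) <- "summary.pgls"
  out
}

#' @export
print.summary.pgls <- function(x, ...) {
  cat("Phylogenetic GLS:", deparse(x$formula), "\n")
  cat(sprintf("lambda = %.4f%s | sigma2 = %.5g | df = %d | %s logLik = %.3f\n",
              x$lambda, if (x$lambda_estimated) " (ML)" else " (fixed)",
              x$sigma2, x$df.residual, x$method, x$logLik))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.pgls <- function(object, ...) object$coefficients

#' @export
vcov.pgls <- function(object, ...) object$vcov

#' @export
residuals.pgls <- function(object, ...) object$residuals

#' @export
fitted.pgls <- function(object, ...) object$fitted.values

#' @export
logLik.pgls <- function(object, ...) {
  structure(object$logLik, df = object$p + 2, nobs = object$n,
            class = "logLik")
}

#' @export
nobs.pgls <- function(object, ...) object$n

#' @export
predict.pgls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  tt <- stats::delete.response(stats::terms(object$formula))
  X <- stats::model.matrix(tt, stats::model.frame(tt, as.data.frame(newdata)))
  drop(X %*% object$coefficients)
}

#' Compare nested fits with an F test
#'
#' `F = [(RSS_r - RSS_f) / (p_f - p_r)] / [RSS_f / df_f]`, with residual sums
#' of squares taken on the GLS-whitened scale for phylogenetic fits (both
#' models evaluated under the full model's fitted covariance, so the
#' comparison is between mean structures only). For two `lm` fits this is the
#' standard [stats::anova()] comparison. This is the species-effect ANOVA
#' used to ask whether scaling relationships differ between species.
#'
#' @param full the richer model (`pgls` or `lm`).
#' @param reduced a model whose predictors are a subset of `full`'s, fitted
#'   to the same rows.
#' @return an object of class `"anova_term"`: `F`, `df_num`, `df_den`,
#'   `p_value`.
#' @export
anova_term <- function(full, reduced) {
  if (inherits(full, "lm") && inherits(reduced, "lm")) {
    if (stats::nobs(full) != stats::nobs(reduced)) {
      stop("models fitted to different row sets", call. = FALSE)
    }
    a <- stats::anova(reduced, full)
    out <- list(F = a$F[2], df_num = a$Df[2], df_den = full$df.residual,
                p_value = a$`Pr(>F)`[2])
    if (is.na(out$F)) { # identical models
      out$F <- 0; out$df_num <- 0L; out$p_value <- 1
    }
  } else if (inherits(full, "pgls") && inherits(reduced, "pgls")) {
    if (full$n != reduced$n || !setequal(full$species, reduced$species)) {
      stop("models fitted to different species sets", call. = FALSE)
    }
    if (!all(colnames(reduced$X) %in% colnames(full$X))) {
      stop("reduced model is not nested in the full model", call. = FALSE)
    }
    U <- chol(full$V)
    ord <- match(full$species, reduced$species)
    rss_f <- gls_rss(U, full$X, full$y)
    rss_r <- gls_rss(U, reduced$X[ord, , drop = FALSE], reduced$y[ord])
    dp <- full$p - reduced$p
    if (dp == 0L) {
      out <- list(F = 0, df_num = 0L, df_den = full$df.residual, p_value = 1)
    } else {
      Fv <- ((rss_r - rss_f) / dp) / (rss_f / full$df.residual)
      Fv <- max(Fv, 0)
      out <- list(F = Fv, df_num = dp, df_den = full$df.residual,
                  p_value = stats::pf(Fv, dp, full$df.residual,
                                      lower.tail = FALSE))
    }
  } else {
    stop("'full' and 'reduced' must both be lm or both pgls", call. = FALSE)
  }
  class(out) <- "anova_term"
  out
}

gls_rss <- function(U, X, y) {
  ys <- backsolve(U, y, transpose = TRUE)
  Xs <- backsolve(U, X, transpose = TRUE)
  sum(qr.resid(qr(Xs), ys)^2)
}

#' @export
print.anova_term <- function(x, ...) {
  cat(sprintf("F = %.4f on %d and %d df, p = %.4g\n",
              x$F, x$df_num, x$df_den, x$p_value))
  invisible(x)
}

#' Test a regression slope against a reference value
#'
#' t test of `H0: beta = value` for one coefficient, e.g. the isometry test
#' `beta = 1` of an allometric exponent.
#'
#' @param fit an `lm` or `pgls` fit.
#' @param term coefficient name.
#' @param value null value (default 1, isometry).
#' @return list with `estimate`, `se`, `t`, `df`, `p_value`.
#' @export
slope_test <- function(fit, term, value = 1) {
  if (inherits(fit, "pgls")) {
    est <- fit$coefficients[term]; se <- fit$se[term]; df <- fit$df.residual
  } else {
    cf <- summary(fit)$coefficients
    if (!term %in% rownames(cf)) stop("no term '", term, "'", call. = FALSE)
    est <- cf[term, 1]; se <- cf[term, 2]; df <- fit$df.residual
  }
  if (is.na(est)) stop("no term '", term, "'", call. = FALSE)
  tv <- (est - value) / se
  list(estimate = unname(est), se = unname(se), t = unname(tv), df = df,
       p_value = unname(2 * stats::pt(-abs(tv), df)))
}

#' Fit an allometric model by column names
#'
#' Convenience wrapper building `response ~ predictors (+ species)` and
#' dispatching to [stats::lm()] or [pgls()]. With `species_fixed = TRUE` the
#' species label enters as treatment-coded dummies (reference level:
#' alphabetically first species), the usual way to give every species its own
#' elevation in a pooled individual-level model.
#'
#' @param table a [trait_table()] or data frame.
#' @param response response column name.
#' @param predictors character vector of predictor columns.
#' @param engine `"ols"` or `"pgls"`.
#' @param species_fixed add species as a fixed factor (OLS only).
#' @param tree,cov,lambda,method passed to [pgls()].
#' @return an `lm` or `pgls` fit.
#' @export
fit_allometry <- function(table, response, predictors,
                          engine = c("ols", "pgls"), species_fixed = FALSE,
                          tree = NULL, cov = NULL, lambda = "ML",
                          method = "REML") {
  engine <- match.arg(engine)
  miss <- setdiff(c(response, predictors), names(table))
  if (length(miss)) {
    stop("column(s) not in table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(table)
  rhs <- paste(c(predictors, if (species_fixed) ".species."), collapse = " + ")
  if (species_fixed) {
    if (engine == "pgls") {
      stop("species_fixed applies to the OLS engine (pgls models have one ",
           "row per species)", call. = FALSE)
    }
    df$.species. <- factor(species_of(table))
  }
  fml <- stats::as.formula(paste(sprintf("`%s`", response), "~",
                                 gsub("\\.species\\.", "`.species.`", rhs)))
  if (engine == "ols") {
    fit <- stats::lm(fml, data = df)
    if (any(is.na(stats::coef(fit)))) {
      stop("rank-deficient design; collinear columns: ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                 collapse = ", "), call. = FALSE)
    }
    fit
  } else {
    if (is.null(tree) && is.null(cov)) {
      stop("engine 'pgls' needs a tree or covariance matrix", call. = FALSE)
    }
    pgls(fml, data = table, tree = tree, cov = cov, lambda = lambda,
         method = method)
  }
}

#' Residuals keyed by observation id
#'
#' @param fit an `lm` or `pgls` fit.
#' @return named numeric vector of ordinary residuals (response log-units).
#' @export
residual_vector <- function(fit) {
  r <- stats::residuals(fit)
  if (is.null(names(r))) names(r) <- as.character(seq_along(r))
  r
}
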