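#' Conditional association between two structures, controlling allometry
#'
#' Fits `focal_y ~ control + focal_x` (optionally plus species dummies).
#' The coefficient on `focal_x` — the partner structure — is the trade-off
#' test: a significantly negative estimate after removing the shared size
#' effect is the signature of an allocation trade-off, while ratio-based
#' indices conflate this with ordinary allometry.
#'
#' @param table a [trait_table()] whose focal columns are on the log scale.
#' @param focal_y,focal_x,control column names (response, partner structure,
#'   allometric control).
#' @param engine `"ols"` or `"pgls"`.
#' @param species_fixed add species dummies (individual-level OLS models).
#' @param tree,cov,lambda passed to [pgls()] when `engine = "pgls"`.
#' @return the `lm` or `pgls` fit, with attribute `"focal_term"` naming the
#'   coefficient that carries the trade-off test.
#' @export
conditional_association <- function(table, focal_y, focal_x, control,
                                    engine = c("ols", "pgls"),
                                    species_fixed = FALSE, tree = NULL,
                                    cov = NULL, lambda = "ML") {
  engine <- match.arg(engine)
  fit <- fit_allometry(table, focal_y, c(control, focal_x), engine = engine,
                       species_fixed = species_fixed, tree = tree, cov = cov,
                       lambda = lambda)
  attr(fit, "focal_term") <- focal_x
  fit
}

#' Extract the focal coefficient of an association fit
#'
#' @param fit a fit carrying a `"focal_term"` attribute, or any `lm`/`pgls`
#'   fit with `term` given explicitly.
#' @param term coefficient name; defaults to the fit's focal term.
#' @return list with `estimate`, `se`, `t`, `df`, `p_value`.
#' @export
focal_coef <- function(fit, term = attr(fit, "focal_term")) {
  if (is.null(term)) stop("no focal term recorded; supply 'term'",
                          call. = FALSE)
  slope_test(fit, term, value = 0)
}

#' Residual-association trade-off test
#'
#' The two-stage construction: regress each focal trait on the allometric
#' control (with the chosen engine), then regress the residuals of A on the
#' residuals of B with the same engine. A negative second-stage slope is the
#' trade-off signature; a positive one indicates concerted variation beyond
#' shared allometry.
#'
#' @inheritParams conditional_association
#' @param trait_a,trait_b focal trait columns (log scale).
#' @return the second-stage `lm` or `pgls` fit; attributes `"stage1_a"` and
#'   `"stage1_b"` hold the first-stage fits, `"focal_term"` the residual-B
#'   slope term.
#' @export
residual_association <- function(table, trait_a, trait_b, control,
                                 engine = c("ols", "pgls"), tree = NULL,
                                 cov = NULL, lambda = "ML") {
  engine <- match.arg(engine)
  f_a <- fit_allometry(table, trait_a, control, engine = engine, tree = tree,
                       cov = cov, lambda = lambda)
  f_b <- fit_allometry(table, trait_b, control, engine = engine, tree = tree,
                       cov = cov, lambda = lambda)
  ra <- residual_vector(f_a)
  rb <- residual_vector(f_b)
  shared <- intersect(names(ra), names(rb))
  rdf <- data.frame(species = shared, res_a = ra[shared], res_b = rb[shared],
                    stringsAsFactors = FALSE)
  rownames(rdf) <- shared
  rtab <- trait_table(rdf, species_col = "species")
  fit <- fit_allometry(rtab, "res_a", "res_b", engine = engine, tree = tree,
                       cov = cov, lambda = lambda)
  attr(fit, "focal_term") <- "res_b"
  attr(fit, "stage1_a") <- f_a
  attr(fit, "stage1_b") <- f_b
  fit
}

#' Ratio-versus-size diagnostic
#'
#' Regresses the log trait ratio (numerator/denominator, computed on the raw
#' scale) on a log size variable. Under isometry of the two traits the ratio
#' carries no size signal; a significant coefficient means the ratio retains
#' allometric structure and is a biased index of relative investment.
#'
#' @inheritParams conditional_association
#' @param numerator,denominator,against column names; `against` is the size
#'   variable (it may also be the numerator itself, to ask whether the ratio
#'   simply tracks its dominant component).
#' @return an `lm` or `pgls` fit of `log(ratio) ~ log(against)` with
#'   `"focal_term"` set to the `against` term.
#' @export
ratio_size_test <- function(table, numerator, denominator, against,
                            engine = c("ols", "pgls"), tree = NULL,
                            cov = NULL, lambda = "ML") {
  engine <- match.arg(engine)
  num <- raw_values(table, numerator)
  den <- raw_values(table, denominator)
  if (any(den == 0, na.rm = TRUE)) stop("zero denominator", call. = FALSE)
  if (any(num <= 0, na.rm = TRUE) || any(den < 0, na.rm = TRUE)) {
    stop("ratio traits must be positive on the raw scale", call. = FALSE)
  }
  base <- attr(table, "log_base") %||% 10
  df <- data.frame(species = species_of(table),
                   log_ratio = log(num / den, base = base),
                   log_against = log_values(table, against),
                   stringsAsFactors = FALSE)
  rownames(df) <- rownames(table)
  rtab <- trait_table(df, species_col = "species")
  fit <- fit_allometry(rtab, "log_ratio", "log_against", engine = engine,
                       tree = tree, cov = cov, lambda = lambda)
  attr(fit, "focal_term") <- "log_against"
  attr(fit, "ratio") <- stats::setNames(num / den, rownames(table))
  fit
}

#' Trait reallocations producing the same ratio
#'
#' Decomposes a change of the trait ratio `e/f` from `e0/f0` to
#' `target_ratio` into three scenarios that are indistinguishable by the
#' ratio alone: (1) a trade-off, splitting the change between an increase of
#' the numerator and a decrease of the denominator (equally in log space by
#' default); (2) a pure numerator increase; (3) a pure denominator decrease.
#' Each returned pair satisfies `e/f = target_ratio` exactly.
#'
#' @param e0,f0 starting trait values (> 0).
#' @param target_ratio target value of `e/f` (> 0).
#' @param split fraction of the log-scale change assigned to the numerator
#'   in the trade-off scenario (default 0.5).
#' @return a data frame with rows `tradeoff`, `numerator_increase`,
#'   `denominator_decrease` and columns `e`, `f`, `ratio`.
#' @examples
#' ratio_scenarios(5.54, 1, 11.81)
#' @export
ratio_scenarios <- function(e0, f0, target_ratio, split = 0.5) {
  if (any(c(e0, f0, target_ratio) <= 0)) {
    stop("e0, f0 and target_ratio must be positive", call. = FALSE)
  }
  k <- target_ratio / (e0 / f0)
  out <- data.frame(
    scenario = c("tradeoff", "numerator_increase", "denominator_decrease"),
    e = c(e0 * k^split, e0 * k, e0),
    f = c(f0 / k^(1 - split), f0, f0 / k),
    stringsAsFactors = FALSE)
  out$ratio <- out$e / out$f
  out
}

#' Classify pairwise elevation shifts of two structures
#'
#' Joins the pairwise elevation-shift matrices of two structures (e.g. a
#' visual and an olfactory structure, each scaled against the same control)
#' and labels every species pair: `"minor"` if either structure's shift is
#' below `min_shift` in absolute value; `"inverse"` if the two structures
#' shift in opposite directions (the trade-off signature); `"single_structure"`
#' if exactly one structure shows a significant shift; `"same_direction"` if
#' both shift the same way; `"none"` otherwise. By default `"inverse"`
#' requires opposite signs and both shifts >= `min_shift` but not dual
#' significance; `strict = TRUE` additionally requires `p < alpha` in both
#' structures. Counts under both rules are returned.
#'
#' @param pair_a,pair_b `shift_matrix` objects from [pairwise_elevation()]
#'   for the two structures, with identical group sets and ordering.
#' @param min_shift minimum absolute elevation difference (log units) for a
#'   shift to count as non-minor (default 0.1).
#' @param alpha significance threshold for the pairwise Wald tests.
#' @param strict require dual significance for `"inverse"`.
#' @return an object of class `"shift_classification"`: a data frame `pairs`
#'   (one row per unordered pair with deltas, p-values and `label`), counts
#'   `n_inverse`, `n_inverse_strict`, `n_pairs`, and the rule parameters.
#' @export
classify_shifts <- function(pair_a, pair_b, min_shift = 0.1, alpha = 0.05,
                            strict = FALSE) {
  if (!identical(pair_a$groups, pair_b$groups)) {
    stop("shift matrices have different group sets/ordering", call. = FALSE)
  }
  da <- as.data.frame(pair_a)
  db <- as.data.frame(pair_b)
  stopifnot(identical(da$group_i, db$group_i))
  n_pairs <- nrow(da)
  lab <- character(n_pairs)
  inv_lenient <- inv_strict <- logical(n_pairs)
  for (k in seq_len(n_pairs)) {
    dA <- da$delta_elevation[k]; dB <- db$delta_elevation[k]
    pA <- da$p[k]; pB <- db$p[k]
    opposite <- sign(dA) * sign(dB) < 0
    big <- abs(dA) >= min_shift && abs(dB) >= min_shift
    inv_lenient[k] <- opposite && big
    inv_strict[k] <- opposite && big && pA < alpha && pB < alpha
    if (abs(dA) < min_shift || abs(dB) < min_shift) {
      lab[k] <- "minor"
    } else if (if (strict) inv_strict[k] else inv_lenient[k]) {
      lab[k] <- "inverse"
    } else if (xor(pA < alpha, pB < alpha)) {
      lab[k] <- "single_structure"
    } else if (sign(dA) == sign(dB)) {
      lab[k] <- "same_direction"
    } else {
      lab[k] <- "none"
    }
  }
  pairs <- data.frame(group_i = da$group_i, group_j = da$group_j,
                      delta_a = da$delta_elevation,
                      delta_b = db$delta_elevation,
                      p_a = da$p, p_b = db$p, label = lab,
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 n_inverse = sum(lab == "inverse"),
                 n_inverse_lenient = sum(inv_lenient),
                 n_inverse_strict = sum(inv_strict),
                 n_pairs = n_pairs, min_shift = min_shift, alpha = alpha,
                 strict = strict),
            class = "shift_classification")
}

#' @export
print.shift_classification <- function(x, ...) {
  cat("Pairwise shift classification (", x$n_pairs, " pairs):\n", sep = "")
  print(table(x$pairs$label))
  cat(sprintf("inverse shifts: %d of %d (strict, dual-significance rule: %d)\n",
              x$n_inverse_lenient, x$n_pairs, x$n_inverse_strict))
  invisible(x)
}

#' Correlation of pairwise elevation differences across two structures
#'
#' Pearson correlation of the upper-triangle elevation differences of
#' structure A against structure B. A strongly negative value would suggest
#' a general tendency for the two structures to shift in opposite
#' directions. The pairs share species, so they are not independent; the
#' result is tagged exploratory and should not be read as a formal test.
#'
#' @inheritParams classify_shifts
#' @return list: `correlation`, `n_pairs`, `caveats`.
#' @export
elevation_diff_correlation <- function(pair_a, pair_b) {
  if (!identical(pair_a$groups, pair_b$groups)) {
    stop("shift matrices have different group sets/ordering", call. = FALSE)
  }
  dA <- pair_a$delta[upper.tri(pair_a$delta)]
  dB <- pair_b$delta[upper.tri(pair_b$delta)]
  if (length(dA) < 3) stop("need at least 3 pairs", call. = FALSE)
  list(correlation = stats::cor(dA, dB), n_pairs = length(dA),
       caveats = paste("exploratory: pairwise differences share species and",
                       "are not phylogenetically independent"))
}

#' Full trade-off report for one dataset
#'
#' Runs the complete framework on one table: conditional association,
#' residual association, grouped SMA with pairwise shift matrices for both
#' structures against the control, shift classification, the
#' elevation-difference correlation, and (when a size column is given) the
#' ratio diagnostics.
#'
#' @inheritParams conditional_association
#' @param trait_a,trait_b focal structure columns (log scale).
#' @param control allometric control column.
#' @param dataset label for the report.
#' @param min_shift,alpha classification thresholds.
#' @param size optional size column for [ratio_size_test()]; defaults to the
#'   numerator (`trait_a`).
#' @param sma_pairwise run the SMA stage (needs >= 2 groups with n >= 3).
#' @return an object of class `"tradeoff_report"`.
#' @export
tradeoff_report <- function(table, trait_a, trait_b, control,
                            engine = c("ols", "pgls"), tree = NULL,
                            cov = NULL, lambda = "ML",
                            species_fixed = FALSE, dataset = "dataset",
                            min_shift = 0.1, alpha = 0.05, size = trait_a,
                            sma_pairwise = TRUE) {
  engine <- match.arg(engine)
  cond <- conditional_association(table, trait_a, trait_b, control,
                                  engine = engine,
                                  species_fixed = species_fixed, tree = tree,
                                  cov = cov, lambda = lambda)
  resid <- residual_association(table, trait_a, trait_b, control,
                                engine = engine, tree = tree, cov = cov,
                                lambda = lambda)
  ratio <- ratio_size_test(table, trait_a, trait_b, size, engine = engine,
                           tree = tree, cov = cov, lambda = lambda)
  sma_a <- sma_b <- cls <- ecor <- NULL
  if (sma_pairwise) {
    tabs <- table(species_of(table))
    if (length(tabs) >= 2 && all(tabs >= 3)) {
      fml_a <- stats::as.formula(paste(trait_a, "~", control))
      fml_b <- stats::as.formula(paste(trait_b, "~", control))
      sma_a <- sma_group(fml_a, table, alpha = alpha)
      sma_b <- sma_group(fml_b, table, alpha = alpha)
      pa <- pairwise_elevation(sma_a)
      pb <- pairwise_elevation(sma_b)
      cls <- classify_shifts(pa, pb, min_shift = min_shift, alpha = alpha)
      ecor <- tryCatch(elevation_diff_correlation(pa, pb),
                       error = function(e) NULL)
    }
  }
  structure(list(dataset = dataset,
                 conditional = focal_coef(cond), conditional_fit = cond,
                 residual = focal_coef(resid), residual_fit = resid,
                 ratio = focal_coef(ratio), ratio_fit = ratio,
                 sma_a = sma_a, sma_b = sma_b,
                 classification = cls, elevation_diff_cor = ecor,
                 alpha = alpha),
            class = "tradeoff_report")
}

#' @export
print.tradeoff_report <- function(x, ...) {
  cat("Trade-off report:", x$dataset, "\n")
  fmt <- function(z) sprintf("beta = %.4f, t(df=%d) = %.3f, p = %.4g",
                             z$estimate, z$df, z$t, z$p_value)
  cat("  conditional association (partner | control):", fmt(x$conditional), "\n")
  cat("  residual association:                       ", fmt(x$residual), "\n")
  cat("  ratio vs size:                              ", fmt(x$ratio), "\n")
  if (!is.null(x$classification)) {
    cat(sprintf("  inverse elevation shifts: %d of %d pairs\n",
                x$classification$n_inverse_lenient, x$classification$n_pairs))
  }
  if (!is.null(x$elevation_diff_cor)) {
    cat(sprintf("  elevation-difference correlation: %.3f (%s)\n",
                x$elevation_diff_cor$correlation,
                x$elevation_diff_cor$caveats))
  }
  dir <- if (x$conditional$estimate < 0 && x$conditional$p_value < x$alpha) {
    "negative (trade-off-like)"
  } else if (x$conditional$p_value < x$alpha) {
    "positive (concerted variation)"
  } else "no significant association"
  cat("  verdict:", dir, "\n")
  invisible(x)
}

#' Rest-of-structure allometric control
#'
#' Builds the independent size control for a dissected structure:
#' `total - part_a - part_b` on the raw scale (e.g. rest-of-disc = whole
#' imaginal disc minus eye and antennal portions), appended to the table as
#' a logged column.
#'
#' @param table a [trait_table()].
#' @param total,part_a,part_b column names (raw or logged; raw scale is
#'   recovered automatically).
#' @param name name of the new column.
#' @return the table with the new log-flagged column.
#' @export
add_rest_control <- function(table, total, part_a, part_b, name = "rest") {
  tot <- raw_values(table, total)
  rest <- tot - raw_values(table, part_a) - raw_values(table, part_b)
  if (any(rest <= 0, na.rm = TRUE)) {
    stop("rest control non-positive for row(s) ",
         paste(rownames(table)[which(rest <= 0)], collapse = ", "),
         call. = FALSE)
  }
  base <- attr(table, "log_base") %||% 10
  table[[name]] <- log(rest, base = base)
  fl <- attr(table, "log_flags")
  fl[name] <- "log"
  attr(table, "log_flags") <- fl
  table
}
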