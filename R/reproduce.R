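#' Recompute the headline statistics of the original sensory-structure study
#'
#' Given the archived study data (59-species head sensory measurements with
#' a phylogeny, and the six-species brain and imaginal-disc individual
#' datasets), reruns the full pipeline and returns the headline statistics:
#' the PGLS scaling slope of eye on funiculus surface area with a body-size
#' control, the residual-association slope, the ratio diagnostics (extreme
#' EF ratios and the EF-versus-ESA t statistic), the brain and disc GLM t
#' statistics, the species-effect ANOVA F, the four SMA elevation Wald
#' statistics, and the inverse-shift tally.
#'
#' The archived data (Open Access Data Repository of the Max Planck Society,
#' DOI 10.17617/3.1D) is not redistributed with this package; point the
#' arguments at locally prepared tables. PGLS-based quantities are
#' maximum-likelihood estimates and are expected to match MCMC-based
#' published values approximately; SMA/OLS quantities are exact-algorithm
#' statistics.
#'
#' @param species_table [trait_table()] with logged columns `esa`, `fsa`,
#'   `body` (override names via `cols`).
#' @param tree phylogeny covering the species table.
#' @param brain_table individual-level [trait_table()] with logged columns
#'   `ol`, `al`, `rob`.
#' @param disc_table individual-level [trait_table()] with logged columns
#'   `edp`, `adp`, `rod`.
#' @param cols named list overriding the default column names.
#' @param min_shift,alpha classification thresholds.
#' @return named list of statistics; components are `NULL` for datasets not
#'   supplied.
#' @export
reproduce_headline_stats <- function(species_table = NULL, tree = NULL,
                                     brain_table = NULL, disc_table = NULL,
                                     cols = list(), min_shift = 0.1,
                                     alpha = 0.05) {
  cl <- utils::modifyList(list(esa = "esa", fsa = "fsa", body = "body",
                               ol = "ol", al = "al", rob = "rob",
                               edp = "edp", adp = "adp", rod = "rod"), cols)
  out <- list()

  if (!is.null(species_table)) {
    if (is.null(tree)) stop("species-level analyses need a tree", call. = FALSE)
    al <- align_taxa(tree, species_table, quiet = TRUE)
    cond <- conditional_association(al$table, cl$esa, cl$fsa, cl$body,
                                    engine = "pgls", tree = al$tree)
    resid <- residual_association(al$table, cl$esa, cl$fsa, cl$body,
                                  engine = "pgls", tree = al$tree)
    ef <- ratio_size_test(al$table, cl$esa, cl$fsa, cl$esa, engine = "pgls",
                          tree = al$tree)
    ratio <- attr(ef, "ratio")
    out$pgls_esa_fsa_slope <- focal_coef(cond)
    out$residual_slope <- focal_coef(resid)
    out$ef_vs_esa <- focal_coef(ef)
    out$ef_ratio_range <- range(ratio)
  }

  intraspecific <- function(tab, y1, y2, control) {
    fit_joint <- fit_allometry(tab, y1, c(control, y2), engine = "ols",
                               species_fixed = TRUE)
    fit_nosp <- fit_allometry(tab, y1, c(control, y2), engine = "ols")
    fml1 <- stats::as.formula(paste(y1, "~", control))
    fml2 <- stats::as.formula(paste(y2, "~", control))
    sg1 <- sma_group(fml1, tab, alpha = alpha)
    sg2 <- sma_group(fml2, tab, alpha = alpha)
    p1 <- pairwise_elevation(sg1)
    p2 <- pairwise_elevation(sg2)
    cls <- classify_shifts(p1, p2, min_shift = min_shift, alpha = alpha)
    list(joint_partner_t = slope_test(fit_joint, y2, value = 0),
         species_anova = anova_term(fit_joint, fit_nosp),
         wald_a = sg1$elevation_test, wald_b = sg2$elevation_test,
         classification = cls,
         elevation_diff_cor = elevation_diff_correlation(p1, p2))
  }

  if (!is.null(brain_table)) {
    out$brain <- intraspecific(brain_table, cl$ol, cl$al, cl$rob)
    out$ol_rob_t <- slope_test(
      fit_allometry(brain_table, cl$ol, cl$rob, engine = "ols",
                    species_fixed = TRUE), cl$rob, value = 0)
  }
  if (!is.null(disc_table)) {
    out$disc <- intraspecific(disc_table, cl$edp, cl$adp, cl$rod)
  }
  out
}
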