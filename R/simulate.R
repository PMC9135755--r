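#' Simulation configuration for synthetic trait data
#'
#' Bundles the data-generating parameters used by
#' [simulate_species_traits()]: Brownian-motion evolution of log body size on
#' a tree, two focal traits with specified allometric slopes against size,
#' residual deviations with a controllable correlation `rho` (negative =
#' trade-off, zero = independent evolution), optional per-species elevation
#' shifts, and within-species replicate settings.
#'
#' Defaults describe the interspecific study conditions the package is built
#' around: 59 species, allometric slopes of 0.75, residual sd 0.1 (log10
#' units) and a Brownian rate of 0.05 for log size on a depth-1 tree
#' (roughly a 0.22 log10-unit spread of body size across the clade).
#'
#' @param n_tips number of species (>= 3).
#' @param seed integer seed; the generator derives independent sub-streams
#'   for the size trait, the residual deviations and individual noise.
#' @param size_sigma2 Brownian rate of log size per unit depth.
#' @param slope_a,slope_b allometric exponents of traits A and B on size.
#' @param intercept_a,intercept_b allometric intercepts (log10 units).
#' @param sigma_a,sigma_b residual standard deviations at the tips.
#' @param rho residual correlation between traits A and B in `[-1, 1]`.
#' @param residual_mode `"phylogenetic"` (deviations evolve as bivariate
#'   Brownian motion, so a trade-off is heritable along the tree) or
#'   `"independent"` (iid deviations per tip).
#' @param elevation_shifts optional list with named numeric vectors `a`
#'   and/or `b` of per-species elevation offsets.
#' @param n_individuals replicates per species for individual-level data.
#' @param individual_sd within-species residual sd.
#' @param log_base log base of the generated log columns.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_tips = 59, seed = 1, size_sigma2 = 0.05,
                       slope_a = 0.75, slope_b = 0.75,
                       intercept_a = 0, intercept_b = 0,
                       sigma_a = 0.1, sigma_b = 0.1, rho = 0,
                       residual_mode = c("phylogenetic", "independent"),
                       elevation_shifts = NULL,
                       n_individuals = 6, individual_sd = 0.05,
                       log_base = 10) {
  residual_mode <- match.arg(residual_mode)
  if (abs(rho) > 1) stop("rho must be in [-1, 1]", call. = FALSE)
  if (n_tips < 3) stop("n_tips must be >= 3", call. = FALSE)
  if (any(c(size_sigma2, sigma_a, sigma_b, individual_sd) < 0)) {
    stop("rates and standard deviations must be >= 0", call. = FALSE)
  }
  structure(list(n_tips = as.integer(n_tips), seed = as.integer(seed),
                 size_sigma2 = size_sigma2, slope_a = slope_a,
                 slope_b = slope_b, intercept_a = intercept_a,
                 intercept_b = intercept_b, sigma_a = sigma_a,
                 sigma_b = sigma_b, rho = rho,
                 residual_mode = residual_mode,
                 elevation_shifts = elevation_shifts,
                 n_individuals = as.integer(n_individuals),
                 individual_sd = individual_sd, log_base = log_base),
            class = "sim_config")
}

# deterministic sub-stream seeds so adding one draw does not shift others
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 2011L + offset
}

#' Simulate a pure-birth phylogeny
#'
#' Yule tree with `n_tips` tips, depth normalized to 1 so Brownian rates are
#' per unit tree depth. Reproducible: the same seed gives the same Newick
#' string.
#'
#' @param n_tips number of tips (>= 3).
#' @param seed integer seed.
#' @return a `"phylo"` object with tip labels `s01, s02, ...`.
#' @export
simulate_tree <- function(n_tips, seed = 1) {
  if (n_tips < 3) stop("n_tips must be >= 3", call. = FALSE)
  set.seed(derive_seed(seed, 1L))
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("s%02d", seq_len(n_tips))
  tree
}

# one Brownian trait on the tree, root value 0
bm_trait <- function(tree, sigma2) {
  if (sigma2 == 0) {
    return(stats::setNames(rep(0, ape::Ntip(tree)), tree$tip.label))
  }
  ape::rTraitCont(tree, model = "BM", sigma = sqrt(sigma2), root.value = 0)
}

#' Simulate species-level traits on a phylogeny
#'
#' Generates `log size` by Brownian motion, then traits A and B as
#' `log A = intercept_a + slope_a * log size + eps_A` (and likewise B), with
#' `(eps_A, eps_B)` correlated at `rho` and either evolved as bivariate
#' Brownian motion on the tree or drawn independently per tip. Per-species
#' elevation shifts are added last. Identical config and seed give
#' bit-identical tables.
#'
#' @param tree a `"phylo"` object; tip labels become species names.
#' @param config a [sim_config()].
#' @return a [trait_table()] with raw-scale columns `body`, `esa`, `fsa`
#'   (generic size, trait A, trait B) flagged as logged — i.e. the stored
#'   values are on the log scale of `config$log_base` — plus the true
#'   deviations `eps_a`, `eps_b` for diagnostics.
#' @export
simulate_species_traits <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- ape::Ntip(tree)
  sp <- tree$tip.label
  depth <- max(ape::node.depth.edgelength(tree))

  set.seed(derive_seed(config$seed, 2L))
  ls <- bm_trait(tree, config$size_sigma2)[sp]

  set.seed(derive_seed(config$seed, 3L))
  if (config$residual_mode == "phylogenetic") {
    # unit-rate BM gives tip variance = depth; rescale to tip sd sigma
    z1 <- bm_trait(tree, 1)[sp] / sqrt(depth)
    z2 <- bm_trait(tree, 1)[sp] / sqrt(depth)
  } else {
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    names(z1) <- names(z2) <- sp
  }
  eps_a <- config$sigma_a * z1
  eps_b <- config$sigma_b * (config$rho * z1 + sqrt(1 - config$rho^2) * z2)

  shift_a <- shift_b <- stats::setNames(rep(0, n), sp)
  es <- config$elevation_shifts
  if (!is.null(es)) {
    if (!is.null(es$a)) shift_a[names(es$a)] <- es$a
    if (!is.null(es$b)) shift_b[names(es$b)] <- es$b
  }

  la <- config$intercept_a + config$slope_a * ls + eps_a + shift_a
  lb <- config$intercept_b + config$slope_b * ls + eps_b + shift_b

  df <- data.frame(species = sp, body = ls, esa = la, fsa = lb,
                   eps_a = unname(eps_a), eps_b = unname(eps_b),
                   stringsAsFactors = FALSE)
  rownames(df) <- sp
  out <- trait_table(df, species_col = "species", log_cols = character(),
                     log_base = config$log_base)
  # generated values are already on the log scale; flag them so raw_values()
  # back-transforms correctly
  fl <- attr(out, "log_flags")
  fl[c("body", "esa", "fsa")] <- "log"
  attr(out, "log_flags") <- fl
  out
}

#' Simulate individual-level trait data within species
#'
#' For intraspecific SMA analyses: each species gets `n_individuals` draws
#' with `x` uniform on the species' x-range and
#' `y = elevation + common_slope * x + noise`. The result feeds straight
#' into [sma_group()] and the shift-matrix machinery.
#'
#' @param species_params data frame with columns `species`, `elevation`,
#'   `x_min`, `x_max`.
#' @param common_slope shared within-species slope.
#' @param individual_sd residual sd of `y` around the species line.
#' @param n_individuals individuals per species (>= 3; the field's datasets
#'   run at 4-8).
#' @param seed integer seed.
#' @param y_name,x_name column names of the generated traits.
#' @return a [trait_table()] of individuals (log-scale values, flagged).
#' @export
simulate_individuals <- function(species_params, common_slope,
                                 individual_sd = 0.05, n_individuals = 6,
                                 seed = 1, y_name = "y", x_name = "x") {
  stopifnot(all(c("species", "elevation", "x_min", "x_max") %in%
                  names(species_params)))
  if (n_individuals < 3) stop("n_individuals must be >= 3", call. = FALSE)
  rows <- vector("list", nrow(species_params))
  for (i in seq_len(nrow(species_params))) {
    p <- species_params[i, ]
    set.seed(derive_seed(seed, 100L + i))
    x <- stats::runif(n_individuals, p$x_min, p$x_max)
    y <- p$elevation + common_slope * x +
      stats::rnorm(n_individuals, sd = individual_sd)
    rows[[i]] <- data.frame(species = p$species, x = x, y = y,
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  names(df)[names(df) == "x"] <- x_name
  names(df)[names(df) == "y"] <- y_name
  rownames(df) <- sprintf("%s_%02d", df$species,
                          stats::ave(seq_len(nrow(df)), df$species,
                                     FUN = seq_along))
  out <- trait_table(df, species_col = "species")
  fl <- attr(out, "log_flags")
  fl[c(x_name, y_name)] <- "log"
  attr(out, "log_flags") <- fl
  out
}

#' Named preset simulation scenarios
#'
#' The canned data-generating scenarios used throughout the package's
#' validation: `tradeoff_strong` (residual correlation -0.7 — the trade-off
#' world), `independent` (rho = 0), `hyperallometric_no_tradeoff`
#' (trait A hyper-allometric at slope 1.3, rho = 0 — the scenario in which
#' ratio-based analyses flag spurious trade-off-like signal), and
#' `conserved_slope_shifted_elevations` (six species sharing a slope but
#' differing in elevation, Fig.-2-style individual data).
#'
#' @param seed base seed recorded in each config.
#' @return a named list; the first three are [sim_config()]s, the last a
#'   list with `species_params`, `common_slope`, `individual_sd`,
#'   `n_individuals`, `seed` for [simulate_individuals()].
#' @export
preset_scenarios <- function(seed = 1) {
  list(
    tradeoff_strong = sim_config(seed = seed, rho = -0.7),
    independent = sim_config(seed = seed, rho = 0),
    hyperallometric_no_tradeoff = sim_config(seed = seed, slope_a = 1.3,
                                             rho = 0),
    conserved_slope_shifted_elevations = list(
      species_params = data.frame(
        species = sprintf("sp%d", 1:6),
        elevation = c(0, 0.15, -0.2, 0.4, 0, -0.15),
        x_min = rep(1.0, 6), x_max = rep(1.6, 6)),
      common_slope = 0.75, individual_sd = 0.05, n_individuals = 6,
      seed = seed)
  )
}
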