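#' Read a pipeline run configuration
#'
#' A run configuration is a YAML file with input paths (`tree`,
#' `species_table`, `individual_table`), column mappings (`columns`:
#' `focal_a`, `focal_b`, `control`, `species`), `log_cols`, engine options
#' (`engine`: `type`, `lambda`, `log_base`), `thresholds` (`alpha`,
#' `min_shift`), `output_dir` and `seed`. Reading then writing a config
#' reproduces it (round-trippable).
#'
#' @param path YAML file path.
#' @return a list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config a run-config list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_run_config <- function(cfg) {
  defaults <- list(
    seed = 1L, output_dir = "allomtrade_out",
    columns = list(focal_a = "esa", focal_b = "fsa", control = "body",
                   species = "species"),
    log_cols = c("esa", "fsa", "body"),
    engine = list(type = "pgls", lambda = "ML", log_base = 10),
    thresholds = list(alpha = 0.05, min_shift = 0.1))
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) {
      cfg[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]])) {
      for (k2 in names(defaults[[k]])) {
        if (is.null(cfg[[k]][[k2]])) cfg[[k]][[k2]] <- defaults[[k]][[k2]]
      }
    }
  }
  if (!cfg$engine$type %in% c("ols", "pgls")) {
    stop("engine type must be 'ols' or 'pgls'", call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

load_config_inputs <- function(cfg) {
  out <- list(tree = NULL, species_table = NULL, individual_table = NULL)
  if (!is.null(cfg$tree)) out$tree <- read_newick(cfg$tree)
  rd <- function(path) {
    tab <- read_trait_table(path, species_col = cfg$columns$species,
                            log_cols = intersect(cfg$log_cols,
                                                 scan_header(path)),
                            log_base = cfg$engine$log_base)
    miss <- setdiff(unlist(cfg$columns[c("focal_a", "focal_b", "control")]),
                    names(tab))
    if (length(miss)) {
      stop("configured column(s) missing from ", path, ": ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    tab
  }
  if (!is.null(cfg$species_table)) out$species_table <- rd(cfg$species_table)
  if (!is.null(cfg$individual_table)) {
    out$individual_table <- rd(cfg$individual_table)
  }
  out
}

scan_header <- function(path) {
  ln <- readLines(path, n = 20L)
  ln <- ln[!startsWith(ln, "#")][1]
  sep <- if (grepl("\t", ln)) "\t" else ","
  strsplit(ln, sep)[[1]]
}

#' Write a trait table as CSV (raw measurement scale)
#'
#' Log-flagged columns are back-transformed so the file holds raw
#' measurements; `comment` lines (provenance: seed, config hash) are written
#' as `#`-prefixed header lines that [read_trait_table()] skips.
#'
#' @param table a [trait_table()].
#' @param path output path.
#' @param comment character vector of provenance lines.
#' @return `path`, invisibly.
#' @export
write_trait_csv <- function(table, path, comment = character()) {
  df <- as.data.frame(table)
  fl <- attr(table, "log_flags")
  base <- attr(table, "log_base") %||% 10
  for (cl in names(fl)[fl == "log"]) df[[cl]] <- base^df[[cl]]
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste("#", comment), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Flatten a fit to a coefficient table
#'
#' @param fit an `lm` or `pgls` fit.
#' @return data frame with columns `term`, `estimate`, `se`, `t`, `df`, `p`.
#' @export
fit_to_df <- function(fit) {
  if (inherits(fit, "pgls")) {
    data.frame(term = names(fit$coefficients),
               estimate = unname(fit$coefficients), se = unname(fit$se),
               t = unname(fit$tstat), df = fit$df.residual,
               p = unname(fit$pval), row.names = NULL)
  } else {
    cf <- summary(fit)$coefficients
    data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
               t = cf[, 3], df = fit$df.residual, p = cf[, 4],
               row.names = NULL)
  }
}

run_log <- function(cfg, lines, file = "run_log.txt") {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(paste("allomtrade", as.character(utils::packageVersion("allomtrade"))),
           paste("date:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           paste("seed:", cfg$seed),
           paste("engine:", cfg$engine$type, "| lambda:", cfg$engine$lambda,
                 "| log base:", cfg$engine$log_base))
  writeLines(c(hdr, "", lines), file.path(cfg$output_dir, file))
  write_run_config(cfg, file.path(cfg$output_dir, "config_resolved.yaml"))
  invisible(NULL)
}

engine_args <- function(cfg, tree) {
  if (cfg$engine$type == "pgls") {
    list(engine = "pgls", tree = tree, lambda = cfg$engine$lambda)
  } else {
    list(engine = "ols")
  }
}

#' Simulate a preset scenario to files
#'
#' Writes the tree (Newick) and trait tables (CSV, raw scale, provenance
#' header) for one named preset from [preset_scenarios()].
#'
#' @param preset preset name.
#' @param seed integer seed (mandatory).
#' @param output_dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
run_simulate <- function(preset, seed, output_dir = "allomtrade_out") {
  presets <- preset_scenarios(seed)
  if (!preset %in% names(presets)) {
    stop("unknown preset '", preset, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  ps <- presets[[preset]]
  files <- c()
  tag <- c(paste("preset:", preset), paste("seed:", seed),
           paste("config:", paste(deparse(unclass(ps)), collapse = " ")))
  if (inherits(ps, "sim_config")) {
    tree <- simulate_tree(ps$n_tips, seed = ps$seed)
    tab <- simulate_species_traits(tree, ps)
    tf <- file.path(output_dir, paste0(preset, "_tree.nwk"))
    cf <- file.path(output_dir, paste0(preset, "_species.csv"))
    write_newick(tree, tf)
    write_trait_csv(tab, cf, comment = tag)
    files <- c(tree = tf, species_table = cf)
  } else {
    tab <- simulate_individuals(ps$species_params, ps$common_slope,
                                ps$individual_sd, ps$n_individuals,
                                seed = ps$seed)
    cf <- file.path(output_dir, paste0(preset, "_individuals.csv"))
    write_trait_csv(tab, cf, comment = tag)
    files <- c(individual_table = cf)
  }
  files
}

#' Run the allometric regressions of a configuration
#'
#' Fits `focal_a ~ control`, `focal_b ~ control` and the joint
#' `focal_a ~ control + focal_b` with the configured engine; writes
#' coefficient and residual CSVs plus a run log.
#'
#' @param config a `run_config` (or path to one).
#' @return invisibly, a named list of the fits.
#' @export
run_allometry <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else
    validate_run_config(config)
  inp <- load_config_inputs(cfg)
  tab <- inp$species_table
  if (is.null(tab)) stop("config has no species_table", call. = FALSE)
  tree <- inp$tree
  dropped <- character()
  if (!is.null(tree)) {
    al <- align_taxa(tree, tab, quiet = TRUE)
    tree <- al$tree; tab <- al$table
    dropped <- c(al$dropped_tips, al$dropped_rows)
  }
  ea <- engine_args(cfg, tree)
  cc <- cfg$columns
  fits <- list(
    a_on_control = do.call(fit_allometry,
                           c(list(tab, cc$focal_a, cc$control), ea)),
    b_on_control = do.call(fit_allometry,
                           c(list(tab, cc$focal_b, cc$control), ea)),
    joint = do.call(fit_allometry,
                    c(list(tab, cc$focal_a, c(cc$control, cc$focal_b)), ea)))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  coefs <- do.call(rbind, lapply(names(fits), function(nm) {
    cbind(model = nm, fit_to_df(fits[[nm]]))
  }))
  utils::write.csv(coefs, file.path(cfg$output_dir, "allometry_coefs.csv"),
                   row.names = FALSE)
  res <- do.call(rbind, lapply(names(fits), function(nm) {
    r <- residual_vector(fits[[nm]])
    data.frame(model = nm, id = names(r), residual = unname(r))
  }))
  utils::write.csv(res, file.path(cfg$output_dir, "allometry_residuals.csv"),
                   row.names = FALSE)
  lam <- vapply(fits, function(f) if (inherits(f, "pgls")) f$lambda else NA_real_,
                numeric(1))
  run_log(cfg, c(
    sprintf("model %s: n = %d, df = %d%s", names(fits),
            vapply(fits, function(f) as.integer(stats::nobs(f)), integer(1)),
            vapply(fits, function(f) as.integer(f$df.residual), integer(1)),
            ifelse(is.na(lam), "", sprintf(", lambda = %.4f", lam))),
    paste("dropped taxa:", if (length(dropped)) paste(dropped, collapse = ", ")
          else "none")), "allometry_log.txt")
  invisible(fits)
}

#' Run the grouped SMA analysis of a configuration
#'
#' Grouped SMA of `focal_a ~ control` and `focal_b ~ control` on the
#' individual-level table, with pairwise elevation matrices written both in
#' long format and as square matrices.
#'
#' @inheritParams run_allometry
#' @return invisibly, list with the two [sma_group()] fits and shift
#'   matrices.
#' @export
run_sma <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else
    validate_run_config(config)
  inp <- load_config_inputs(cfg)
  tab <- inp$individual_table
  if (is.null(tab)) stop("config has no individual_table", call. = FALSE)
  cc <- cfg$columns
  out <- list()
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  lines <- character()
  for (focal in c("focal_a", "focal_b")) {
    fml <- stats::as.formula(paste(cc[[focal]], "~", cc$control))
    sg <- sma_group(fml, tab, alpha = cfg$thresholds$alpha)
    pw <- pairwise_elevation(sg)
    nm <- cc[[focal]]
    utils::write.csv(coef(sg),
                     file.path(cfg$output_dir, paste0("sma_", nm, "_groups.csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(pw),
                     file.path(cfg$output_dir, paste0("sma_", nm, "_pairwise.csv")),
                     row.names = FALSE)
    utils::write.csv(pw$delta,
                     file.path(cfg$output_dir, paste0("sma_", nm, "_delta_matrix.csv")))
    lines <- c(lines, sprintf(
      "%s ~ %s: b_common = %.4f, slope LR = %.3f (df %d, p %.4g), elevation W = %.3f (df %d, p %.4g)",
      nm, cc$control, sg$b_common, sg$slope_test$statistic, sg$slope_test$df,
      sg$slope_test$p_value, sg$elevation_test$W, sg$elevation_test$df,
      sg$elevation_test$p_value))
    out[[nm]] <- list(sma = sg, pairwise = pw)
  }
  run_log(cfg, lines, "sma_log.txt")
  invisible(out)
}

#' Run the full trade-off analysis of a configuration
#'
#' Conditional and residual association on the species-level table and,
#' when an individual-level table is configured, the grouped SMA stage with
#' shift classification; writes the report bundle (coefficients,
#' classification long CSV, square delta matrices, text report, run log).
#'
#' @inheritParams run_allometry
#' @return invisibly, the species-level [tradeoff_report()] (with the
#'   individual-level report attached as `"individual_report"` when
#'   configured).
#' @export
run_tradeoff <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else
    validate_run_config(config)
  inp <- load_config_inputs(cfg)
  cc <- cfg$columns
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  rep_sp <- NULL
  if (!is.null(inp$species_table)) {
    tab <- inp$species_table
    tree <- inp$tree
    if (!is.null(tree)) {
      al <- align_taxa(tree, tab, quiet = TRUE)
      tree <- al$tree; tab <- al$table
    }
    ea <- engine_args(cfg, tree)
    rep_sp <- do.call(tradeoff_report, c(
      list(tab, cc$focal_a, cc$focal_b, cc$control, dataset = "species-level",
           min_shift = cfg$thresholds$min_shift,
           alpha = cfg$thresholds$alpha, sma_pairwise = FALSE), ea))
  }
  rep_ind <- NULL
  if (!is.null(inp$individual_table)) {
    rep_ind <- tradeoff_report(inp$individual_table, cc$focal_a, cc$focal_b,
                               cc$control, engine = "ols",
                               species_fixed = TRUE,
                               dataset = "individual-level",
                               min_shift = cfg$thresholds$min_shift,
                               alpha = cfg$thresholds$alpha)
  }
  main <- rep_sp %||% rep_ind
  if (is.null(main)) stop("config names no input tables", call. = FALSE)

  coefs <- do.call(rbind, lapply(
    Filter(Negate(is.null), list(species = rep_sp, individual = rep_ind)),
    function(r) data.frame(
      dataset = r$dataset,
      test = c("conditional", "residual", "ratio_vs_size"),
      estimate = c(r$conditional$estimate, r$residual$estimate,
                   r$ratio$estimate),
      t = c(r$conditional$t, r$residual$t, r$ratio$t),
      df = c(r$conditional$df, r$residual$df, r$ratio$df),
      p = c(r$conditional$p_value, r$residual$p_value, r$ratio$p_value))))
  utils::write.csv(coefs, file.path(cfg$output_dir, "tradeoff_tests.csv"),
                   row.names = FALSE)
  for (r in Filter(Negate(is.null), list(rep_sp, rep_ind))) {
    if (!is.null(r$classification)) {
      utils::write.csv(r$classification$pairs,
                       file.path(cfg$output_dir, "shift_classification.csv"),
                       row.names = FALSE)
    }
  }
  txt <- unlist(lapply(Filter(Negate(is.null), list(rep_sp, rep_ind)),
                       function(r) utils::capture.output(print(r))))
  writeLines(txt, file.path(cfg$output_dir, "tradeoff_report.txt"))
  run_log(cfg, txt, "tradeoff_log.txt")
  if (!is.null(rep_ind) && !is.null(rep_sp)) {
    attr(main, "individual_report") <- rep_ind
  }
  invisible(main)
}
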