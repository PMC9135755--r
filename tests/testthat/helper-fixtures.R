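# shared fixtures, generated in code

# three-taxon ultrametric tree used by the covariance / PGLS oracles
tiny_tree <- function() read_newick(text = "((A:1,B:1):1,C:2);")

# g identically distributed groups sharing slope and elevation (SMA null)
null_groups <- function(g = 6, n = 30, slope = 0.75, sd = 0.1,
                        xlim = c(1, 2)) {
  lapply(seq_len(g), function(i) {
    x <- stats::runif(n, xlim[1], xlim[2])
    list(x = x, y = slope * x + stats::rnorm(n, sd = sd))
  })
}

# groups with specified elevations at a shared slope
offset_groups <- function(elevations, n = 30, slope = 0.75, sd = 0.1,
                          xlim = c(1, 2)) {
  lapply(elevations, function(a) {
    x <- stats::runif(n, xlim[1], xlim[2])
    list(x = x, y = a + slope * x + stats::rnorm(n, sd = sd))
  })
}

# small species-level table on a simulated tree
sim_table <- function(seed = 1, n_tips = 59, ...) {
  tr <- simulate_tree(n_tips, seed = seed)
  tt <- simulate_species_traits(tr, sim_config(n_tips = n_tips, seed = seed,
                                               ...))
  list(tree = tr, table = tt)
}

write_tmp_csv <- function(df, ext = ".csv") {
  f <- tempfile(fileext = ext)
  utils::write.csv(df, f, row.names = FALSE)
  f
}
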