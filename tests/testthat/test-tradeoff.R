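test_that("ratio_scenarios hits the target ratio exactly in all scenarios", {
  sc <- ratio_scenarios(5.54, 1, 11.81)
  expect_equal(sc$ratio, rep(11.81, 3), tolerance = 1e-12)
  expect_equal(sc$scenario,
               c("tradeoff", "numerator_increase", "denominator_decrease"))
  # trade-off scenario moves both traits, the others move exactly one
  expect_gt(sc$e[1], 5.54); expect_lt(sc$f[1], 1)
  expect_equal(sc$f[2], 1); expect_equal(sc$e[3], 5.54)
  # identity when the target equals the current ratio
  id <- ratio_scenarios(4, 2, 2)
  expect_equal(id$e, rep(4, 3)); expect_equal(id$f, rep(2, 3))
  # applying k then 1/k round-trips
  fwd <- ratio_scenarios(6, 2, 9)
  back <- ratio_scenarios(fwd$e[1], fwd$f[1], 3)
  expect_equal(back$e[1], 6, tolerance = 1e-12)
  expect_equal(back$f[1], 2, tolerance = 1e-12)
  # random valid inputs are exact too, including asymmetric splits
  set.seed(19)
  for (i in 1:20) {
    e0 <- runif(1, 0.1, 50); f0 <- runif(1, 0.1, 50)
    tgt <- runif(1, 0.1, 50); spl <- runif(1)
    expect_equal(ratio_scenarios(e0, f0, tgt, split = spl)$ratio,
                 rep(tgt, 3), tolerance = 1e-12)
  }
  expect_error(ratio_scenarios(-1, 1, 2), "positive")
})

test_that("conditional_association recovers a constructed partial effect", {
  set.seed(20)
  n <- 200
  d <- data.frame(species = sprintf("s%03d", 1:n), control = runif(n, 1, 3))
  d$x <- 0.5 * d$control + rnorm(n, sd = 0.2)
  d$y <- 0.75 * d$control + 0.5 * d$x + rnorm(n, sd = 0.1)
  tt <- trait_table(d)
  fit <- conditional_association(tt, "y", "x", "control", engine = "ols")
  fc <- focal_coef(fit)
  expect_equal(fc$estimate, 0.5, tolerance = 0.1)
  expect_lt(fc$p_value, 1e-6)
  expect_error(conditional_association(tt, "y", "x", "control",
                                       engine = "pgls"), "tree")
})

test_that("conditional_association is null-calibrated given the control", {
  set.seed(22)
  rej <- vapply(1:800, function(i) {
    n <- 50
    control <- runif(n, 1, 3)
    x <- 0.5 * control + rnorm(n, sd = 0.2)
    y <- 0.75 * control + rnorm(n, sd = 0.1) # independent of x given control
    d <- data.frame(species = sprintf("s%02d", 1:n), control = control,
                    x = x, y = y)
    focal_coef(conditional_association(trait_table(d), "y", "x", "control",
                                       engine = "ols"))$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.025)
})

test_that("residual_association detects trade-offs and respects the null", {
  s <- sim_table(seed = 23, rho = -0.9)
  fit <- residual_association(s$table, "esa", "fsa", "body", engine = "pgls",
                              tree = s$tree)
  fc <- focal_coef(fit)
  expect_lt(fc$estimate, 0)
  expect_lt(fc$p_value, 0.01)
  # first-stage fits travel with the result
  expect_s3_class(attr(fit, "stage1_a"), "pgls")
  # independent traits: small effect
  s0 <- sim_table(seed = 24, rho = 0)
  fc0 <- focal_coef(residual_association(s0$table, "esa", "fsa", "body",
                                         engine = "pgls", tree = s0$tree))
  expect_lt(abs(fc0$estimate), 0.35)
})

test_that("ratio_size_test exposes allometric leakage of ratios", {
  # hyper-allometric numerator: log(ratio) grows with size
  s <- sim_table(seed = 25, slope_a = 1.3, rho = 0)
  fc <- focal_coef(ratio_size_test(s$table, "esa", "fsa", "body",
                                   engine = "pgls", tree = s$tree))
  expect_gt(fc$estimate, 0)
  expect_lt(fc$p_value, 0.05)
  # ratio values are carried on the raw scale
  r <- attr(ratio_size_test(s$table, "esa", "fsa", "body"), "ratio")
  expect_equal(unname(r), unname(raw_values(s$table, "esa") /
                                   raw_values(s$table, "fsa")),
               tolerance = 1e-10)
  expect_true(all(r > 0))
})

test_that("classify_shifts applies the sign, magnitude and alpha rules", {
  mk <- function(delta, p, groups = c("g1", "g2", "g3")) {
    g <- length(groups)
    D <- matrix(0, g, g, dimnames = list(groups, groups))
    P <- matrix(1, g, g, dimnames = list(groups, groups))
    D[upper.tri(D)] <- delta
    D <- D - t(D)
    P[upper.tri(P)] <- p
    P[lower.tri(P)] <- t(P)[lower.tri(P)]
    diag(P) <- 0
    W <- qchisq(pmax(1 - P, 0), 1)
    structure(list(groups = groups, delta = D, W = W, p = P,
                   p_holm = P, slope_used = "pairwise", alpha = 0.05),
              class = "shift_matrix")
  }
  # pairs: (1,2) inverse, (1,3) minor in B, (2,3) same direction
  a <- mk(delta = c(1.0, 0.8, 0.5), p = c(0.01, 0.01, 0.01))
  b <- mk(delta = c(-1.0, 0.05, 0.6), p = c(0.01, 0.50, 0.01))
  cls <- classify_shifts(a, b)
  lab <- setNames(cls$pairs$label,
                  paste(cls$pairs$group_i, cls$pairs$group_j))
  expect_equal(lab[["g1 g2"]], "inverse")
  expect_equal(lab[["g1 g3"]], "minor")
  expect_equal(lab[["g2 g3"]], "same_direction")
  expect_equal(cls$n_pairs, 3)
  expect_equal(cls$n_inverse, 1)
  # strict rule demands dual significance
  b2 <- mk(delta = c(-1.0, 0.05, 0.6), p = c(0.50, 0.50, 0.30))
  cls2 <- classify_shifts(a, b2, strict = TRUE)
  expect_equal(cls2$n_inverse, 0)
  expect_equal(cls2$n_inverse_lenient, 1)
  lab2 <- setNames(cls2$pairs$label,
                   paste(cls2$pairs$group_i, cls2$pairs$group_j))
  expect_equal(lab2[["g1 g2"]], "single_structure")
  # group mismatch refused
  c3 <- mk(delta = c(1, 1, 1), p = c(0.01, 0.01, 0.01),
           groups = c("x", "y", "z"))
  expect_error(classify_shifts(a, c3), "group")
})

test_that("classification counts survive relabeling and sign convention flips", {
  set.seed(26)
  df <- do.call(rbind, lapply(1:4, function(i) {
    x <- runif(8, 1, 2)
    data.frame(species = sprintf("sp%d", i), x = x,
               ya = c(0, 0.6, -0.4, 0)[i] + 0.75 * x + rnorm(8, sd = 0.05),
               yb = c(0, -0.5, 0.5, 0)[i] + 0.75 * x + rnorm(8, sd = 0.05))
  }))
  tt <- trait_table(df)
  rownames(tt) <- sprintf("r%02d", seq_len(nrow(df)))
  pa <- pairwise_elevation(suppressWarnings(sma_group(ya ~ x, tt)))
  pb <- pairwise_elevation(suppressWarnings(sma_group(yb ~ x, tt)))
  cls <- classify_shifts(pa, pb)
  # flip both matrices' orientation (delta -> -delta): labels unchanged
  flip <- function(m) { m$delta <- -m$delta; m }
  cls_f <- classify_shifts(flip(pa), flip(pb))
  expect_equal(cls_f$n_inverse, cls$n_inverse)
  expect_equal(table(cls_f$pairs$label), table(cls$pairs$label))
  # relabel groups consistently: counts unchanged
  relabel <- function(m, map) {
    m$groups <- map[m$groups]
    dimnames(m$delta) <- dimnames(m$W) <- dimnames(m$p) <-
      dimnames(m$p_holm) <- list(m$groups, m$groups)
    m
  }
  map <- setNames(sprintf("taxon%d", 1:4), sprintf("sp%d", 1:4))
  cls_r <- classify_shifts(relabel(pa, map), relabel(pb, map))
  expect_equal(cls_r$n_inverse, cls$n_inverse)
  expect_equal(cls_r$n_pairs, cls$n_pairs)
})

test_that("elevation_diff_correlation handles exact and null relations", {
  set.seed(27)
  g <- 5
  nm <- sprintf("sp%d", 1:g)
  D <- matrix(0, g, g, dimnames = list(nm, nm))
  D[upper.tri(D)] <- rnorm(g * (g - 1) / 2)
  D <- D - t(D)
  mk <- function(delta) structure(
    list(groups = nm, delta = delta, W = abs(delta), p = abs(delta),
         p_holm = abs(delta), slope_used = "pairwise", alpha = 0.05),
    class = "shift_matrix")
  expect_equal(elevation_diff_correlation(mk(D), mk(-D))$correlation, -1,
               tolerance = 1e-12)
  expect_equal(elevation_diff_correlation(mk(D), mk(D))$correlation, 1,
               tolerance = 1e-12)
  out <- elevation_diff_correlation(mk(D), mk(-D))
  expect_equal(out$n_pairs, g * (g - 1) / 2)
  expect_match(out$caveats, "not phylogenetically independent")
  # permutation oracle: independent differences correlate near zero on average
  cors <- vapply(1:200, function(i) {
    D2 <- matrix(0, g, g, dimnames = list(nm, nm))
    D2[upper.tri(D2)] <- sample(D[upper.tri(D)])
    D2 <- D2 - t(D2)
    elevation_diff_correlation(mk(D), mk(D2))$correlation
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.1)
  # too few pairs refused
  nm2 <- c("a", "b")
  D3 <- matrix(c(0, -1, 1, 0), 2, dimnames = list(nm2, nm2))
  small <- structure(list(groups = nm2, delta = D3, W = abs(D3), p = abs(D3),
                          p_holm = abs(D3), slope_used = "pairwise",
                          alpha = 0.05), class = "shift_matrix")
  expect_error(elevation_diff_correlation(small, small), "3 pairs")
})

test_that("add_rest_control subtracts parts on the raw scale", {
  d <- data.frame(species = c("a", "b"), total = c(100, 200),
                  edp = c(30, 80), adp = c(20, 40))
  tt <- trait_table(d, log_cols = c("total", "edp", "adp"))
  tt2 <- add_rest_control(tt, "total", "edp", "adp", name = "rod")
  expect_equal(raw_values(tt2, "rod"), c(50, 80), tolerance = 1e-10)
  d$edp <- c(90, 80)
  tt3 <- trait_table(d, log_cols = c("total", "edp", "adp"))
  expect_error(add_rest_control(tt3, "total", "edp", "adp"), "non-positive")
})

test_that("tradeoff_report assembles a coherent verdict", {
  s <- sim_table(seed = 28, rho = -0.8)
  rep <- tradeoff_report(s$table, "esa", "fsa", "body", engine = "pgls",
                         tree = s$tree, dataset = "sim", sma_pairwise = FALSE)
  expect_s3_class(rep, "tradeoff_report")
  expect_lt(rep$residual$estimate, 0)
  out <- capture.output(print(rep))
  expect_true(any(grepl("trade-off|association", out)))
})
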