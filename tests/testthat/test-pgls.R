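test_that("bm_covariance matches brute-force path lengths", {
  C <- bm_covariance(tiny_tree())
  expect_equal(C, matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3,
                         dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  # star tree: diagonal only
  star <- read_newick(text = "(A:1.5,B:1.5,C:1.5,D:1.5);")
  expect_equal(unname(bm_covariance(star)), 1.5 * diag(4))
  # lambda = 0 keeps the diagonal, zeroes the rest
  L0 <- lambda_transform(C, 0)
  expect_equal(unname(L0), diag(diag(C)))
  expect_equal(lambda_transform(C, 1), C)
  expect_error(lambda_transform(C, 1.2), "lambda")
})

test_that("pgls with identity covariance equals OLS exactly", {
  set.seed(5)
  d <- data.frame(species = sprintf("s%02d", 1:25),
                  x = rnorm(25), z = rnorm(25))
  d$y <- 1 + 0.5 * d$x - 0.3 * d$z + rnorm(25, sd = 0.2)
  rownames(d) <- d$species
  C <- diag(25)
  dimnames(C) <- list(d$species, d$species)
  fp <- pgls(y ~ x + z, d, cov = C, lambda = 1)
  fo <- lm(y ~ x + z, d)
  so <- summary(fo)$coefficients
  expect_equal(unname(coef(fp)), unname(coef(fo)), tolerance = 1e-10)
  expect_equal(unname(fp$se), unname(so[, 2]), tolerance = 1e-10)
  expect_equal(unname(fp$tstat), unname(so[, 3]), tolerance = 1e-10)
  expect_equal(fp$df.residual, fo$df.residual)
  expect_equal(unname(fp$residuals), unname(residuals(fo)), tolerance = 1e-10)
  # OLS residuals with intercept sum to zero
  expect_lt(abs(sum(fp$residuals)), 1e-10)
})

test_that("pgls reproduces hand matrix algebra on the 3-taxon tree", {
  C <- bm_covariance(tiny_tree())
  d <- data.frame(species = c("A", "B", "C"), x = c(1, 0, 0), y = c(2, 1, 0))
  fit <- pgls(y ~ x, d, cov = C, lambda = 1)
  X <- cbind(1, d$x)
  V <- C[d$species, d$species]
  beta <- solve(t(X) %*% solve(V) %*% X) %*% t(X) %*% solve(V) %*% d$y
  expect_equal(unname(coef(fit)), drop(beta), tolerance = 1e-12)
  # GLS orthogonality: X' V^-1 (y - X beta) = 0
  r <- d$y - X %*% beta
  expect_lt(max(abs(t(X) %*% solve(V) %*% r)), 1e-10)
  expect_equal(unname(residuals(fit)), drop(r), tolerance = 1e-12)
})

test_that("pgls matches nlme::gls with a fixed Pagel correlation", {
  s <- sim_table(seed = 7, n_tips = 40)
  d <- as.data.frame(s$table)
  for (lam in c(0.4, 1)) {
    fg <- nlme::gls(esa ~ body, data = d,
                    correlation = ape::corPagel(lam, s$tree, form = ~species,
                                                fixed = TRUE),
                    method = "REML")
    fm <- pgls(esa ~ body, s$table, tree = s$tree, lambda = lam,
               method = "REML")
    expect_equal(unname(coef(fm)), unname(coef(fg)), tolerance = 1e-8)
    expect_equal(unname(fm$se), unname(sqrt(diag(vcov(fg)))),
                 tolerance = 1e-8)
    expect_equal(fm$logLik, as.numeric(fg$logLik), tolerance = 1e-8)
  }
})

test_that("noiseless data give exact slope recovery and zero residuals", {
  s <- sim_table(seed = 2, n_tips = 30, sigma_a = 0, sigma_b = 0)
  fit <- pgls(esa ~ body, s$table, tree = s$tree, lambda = "ML")
  expect_equal(unname(coef(fit)[["body"]]), 0.75, tolerance = 1e-8)
  expect_lt(max(abs(residuals(fit))), 1e-8)
  expect_lt(fit$sigma2, 1e-16)
})

test_that("ML lambda recovers Brownian structure and hits boundaries cleanly", {
  lams <- vapply(1:40, function(i) {
    s <- sim_table(seed = 400 + i, n_tips = 100)
    pgls(esa ~ body, s$table, tree = s$tree, lambda = "ML")$lambda
  }, numeric(1))
  expect_gte(median(lams), 0.9)
  # independent tips: lambda should collapse toward zero
  lam0 <- vapply(1:15, function(i) {
    s <- sim_table(seed = 800 + i, n_tips = 80, size_sigma2 = 0,
                   residual_mode = "independent")
    pgls(esa ~ fsa, s$table, tree = s$tree, lambda = "ML")$lambda
  }, numeric(1))
  expect_lt(median(lam0), 0.3)
})

test_that("ols fit recovers exact and grid-constructed coefficients", {
  # y = 2x exactly
  d <- data.frame(species = letters[1:5], x = 1:5, y = 2 * (1:5))
  f <- fit_allometry(trait_table(d), "y", "x", engine = "ols")
  expect_equal(coef(f)[["x"]], 2, tolerance = 1e-12)
  expect_lt(max(abs(residuals(f))), 1e-12)
  expect_lt(suppressWarnings(summary(f)$sigma), 1e-12)
  # y = x + z on a 6-point grid: normal equations oracle
  g <- expand.grid(x = c(0, 1, 2), z = c(0, 1))
  g$y <- g$x + g$z
  g$species <- letters[1:6]
  XtX <- crossprod(cbind(1, g$x, g$z))
  beta <- solve(XtX, crossprod(cbind(1, g$x, g$z), g$y))
  f2 <- fit_allometry(trait_table(g), "y", c("x", "z"), engine = "ols")
  expect_equal(unname(coef(f2)), drop(beta), tolerance = 1e-10)
  expect_equal(coef(f2)[["x"]], 1, tolerance = 1e-10)
  expect_equal(coef(f2)[["z"]], 1, tolerance = 1e-10)
})

test_that("species fixed effects use treatment coding with offsets recovered", {
  d <- data.frame(species = rep(c("a_sp", "b_sp"), each = 10),
                  x = rep(seq(0, 1, length.out = 10), 2))
  d$y <- 0.75 * d$x + ifelse(d$species == "b_sp", 1, 0)
  tt <- trait_table(d, id_col = NULL)
  rownames(tt) <- paste0(d$species, 1:20)
  f <- fit_allometry(tt, "y", "x", engine = "ols", species_fixed = TRUE)
  cf <- coef(f)
  expect_equal(cf[["x"]], 0.75, tolerance = 1e-10)
  expect_equal(unname(cf[grep("b_sp", names(cf))]), 1, tolerance = 1e-10)
  # collinear predictors are refused with names
  d$x2 <- d$x * 2
  expect_error(fit_allometry(trait_table(d), "y", c("x", "x2"),
                             engine = "ols"), "collinear")
})

test_that("anova_term matches its F definition and detects species effects", {
  set.seed(9)
  d <- data.frame(species = rep(sprintf("sp%d", 1:5), each = 8),
                  x = runif(40))
  d$y <- 0.5 * d$x + rnorm(40, sd = 0.1)
  tt <- trait_table(d)
  rownames(tt) <- paste0(d$species, "_", 1:40)
  full <- fit_allometry(tt, "y", "x", engine = "ols", species_fixed = TRUE)
  red <- fit_allometry(tt, "y", "x", engine = "ols")
  a <- anova_term(full, red)
  rss_f <- sum(residuals(full)^2)
  rss_r <- sum(residuals(red)^2)
  expect_equal(a$F, ((rss_r - rss_f) / 4) / (rss_f / full$df.residual),
               tolerance = 1e-10)
  expect_equal(a$df_num, 4)
  # identical models: F = 0, p = 1
  a0 <- anova_term(red, red)
  expect_equal(a0$F, 0)
  expect_equal(a0$p_value, 1)
  # strong constructed offsets: overwhelming F
  d$y2 <- d$y + rep(c(0, 2, 4, 6, 8), each = 8)
  tt2 <- trait_table(d)
  rownames(tt2) <- rownames(tt)
  full2 <- fit_allometry(tt2, "y2", "x", engine = "ols", species_fixed = TRUE)
  red2 <- fit_allometry(tt2, "y2", "x", engine = "ols")
  a2 <- anova_term(full2, red2)
  expect_gt(a2$F, 100)
  expect_lt(a2$p_value, 1e-6)
})

test_that("anova_term F is null-calibrated for a zero-effect term", {
  set.seed(21)
  reps <- 500
  p <- vapply(seq_len(reps), function(i) {
    x <- rnorm(50); z <- rnorm(50)
    y <- 0.5 * x + rnorm(50)
    anova_term(lm(y ~ x + z), lm(y ~ x))$p_value
  }, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.025)
  # p-values roughly uniform
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("isometry test is calibrated and gains power away from beta = 1", {
  rej <- vapply(c(1.0, 0.9, 0.75), function(b) {
    mean(vapply(1:80, function(i) {
      s <- sim_table(seed = round(1000 * b) + i, n_tips = 59, slope_a = b)
      st <- slope_test(pgls(esa ~ body, s$table, tree = s$tree,
                            lambda = "ML"), "body", value = 1)
      st$p_value < 0.05
    }, logical(1)))
  }, numeric(1))
  expect_lt(rej[1], 0.15)          # near-nominal at beta = 1
  expect_gt(rej[3], rej[1])        # power grows with |beta - 1|
  expect_gte(rej[3], rej[2])
  expect_gt(rej[3], 0.6)
})

test_that("pgls refuses duplicated species, bad lambda and missing taxa", {
  s <- sim_table(seed = 3, n_tips = 10)
  d <- as.data.frame(s$table)
  d2 <- rbind(d, d[1, ])
  rownames(d2) <- c(rownames(d), "dup")
  expect_error(pgls(esa ~ body, d2, tree = s$tree, species = "species"),
               "one row per species")
  expect_error(pgls(esa ~ body, d, tree = s$tree, lambda = 2), "lambda")
  d$species[1] <- "not_in_tree"
  expect_error(pgls(esa ~ body, d, tree = s$tree, species = "species"),
               "not_in_tree")
})
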