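test_that("gls_profile reduces to OLS when V is the identity", {
  set.seed(3)
  n <- 40
  x <- rnorm(n); y <- 1.5 - 0.7 * x + rnorm(n)
  X <- cbind(intercept = 1, slope = x)
  g <- gls_profile(y, X, diag(n))
  ols <- lm(y ~ x)
  expect_equal(unname(g$beta), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(g$r2, summary(ols)$r.squared, tolerance = 1e-10)
  sm <- summary(ols)$coefficients
  expect_equal(unname(g$se_beta), unname(sm[, "Std. Error"]),
               tolerance = 1e-10)
})

test_that("gls_profile agrees with the explicit-inverse textbook formula", {
  for (seed in 1:10) {
    set.seed(seed)
    tr <- random_yule(8, seed = seed + 100)
    V <- lambda_transform(phylo_vcv(tr), runif(1))
    x <- rnorm(8); y <- rnorm(8)
    X <- cbind(intercept = 1, slope = x)
    g <- gls_profile(y, X, V)

    Vi <- solve(V)
    beta <- solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y
    r <- y - X %*% beta
    s2 <- drop(t(r) %*% Vi %*% r) / 8
    ll <- -0.5 * (8 * log(2 * pi * s2) + determinant(V)$modulus + 8)
    expect_equal(unname(g$beta), as.numeric(beta), tolerance = 1e-10)
    expect_equal(g$sigma2, s2, tolerance = 1e-10)
    expect_equal(g$loglik, as.numeric(ll), tolerance = 1e-8)
  }
})

test_that("gls_profile handles perfect fits and rejects collinear designs", {
  set.seed(5)
  x <- rnorm(20)
  X <- cbind(intercept = 1, slope = x)
  g <- gls_profile(2 + 3 * x, X, diag(20))
  expect_true(g$degenerate)
  expect_equal(g$sigma2, 1e-12)
  expect_true(is.finite(g$loglik))
  expect_equal(unname(g$beta), c(2, 3), tolerance = 1e-8)

  expect_error(gls_profile(rnorm(20), cbind(1, x, x), diag(20)),
               "collinear")
  D <- diag(20); D[1, 1] <- 0
  expect_error(gls_profile(rnorm(20), X, D), "singular|positive definite")
})

test_that("lambda has no effect on a star phylogeny and the fit matches OLS", {
  star <- ape::stree(60, "star")
  star$edge.length <- rep(1, 60)
  star$tip.label <- sprintf("sp%04d", 1:60)
  set.seed(11)
  x <- setNames(rnorm(60), star$tip.label)
  y <- setNames(2 - 0.5 * x + rnorm(60, sd = 0.8), star$tip.label)
  fit <- fit_pgls_lambda(y, x, star)
  ols <- lm(y ~ x)
  expect_equal(unname(fit$beta["slope"]), unname(coef(ols)[2]),
               tolerance = 1e-8)
  expect_equal(unname(fit$beta["intercept"]), unname(coef(ols)[1]),
               tolerance = 1e-8)
  sm <- summary(ols)$coefficients
  expect_equal(fit$p_slope, sm["x", "Pr(>|t|)"], tolerance = 1e-8)
  expect_equal(fit$r2, summary(ols)$r.squared, tolerance = 1e-8)
  expect_equal(sign(fit$t_slope), sign(fit$beta[["slope"]]))
})

test_that("the ML lambda dominates a fine grid and both endpoints", {
  for (seed in 1:4) {
    tr <- random_yule(40, seed = seed)
    sim <- simulate_regression_dataset(tr, slope = 0.75, lam = 0.5,
                                       sigma2 = 1, seed = seed)
    fit <- fit_pgls_lambda(sim$y, sim$x, tr)
    expect_gte(fit$loglik, fit$loglik_lambda0 - 1e-6)
    expect_gte(fit$loglik, fit$loglik_lambda1 - 1e-6)

    V <- phylo_vcv(tr)
    X <- cbind(intercept = 1, slope = sim$x[tr$tip.label])
    yv <- sim$y[tr$tip.label]
    grid_ll <- vapply(seq(0, 1, by = 0.001), function(l)
      gls_profile(yv, X, lambda_transform(V, l))$loglik, numeric(1))
    expect_gte(fit$loglik, max(grid_ll) - 1e-4)
  }
})

test_that("pgls matches the nlme corPagel maximum-likelihood fit", {
  skip_if_not_installed("nlme")
  tr <- random_yule(50, seed = 19)
  sim <- simulate_regression_dataset(tr, slope = -0.6, lam = 0.7,
                                     sigma2 = 0.5, seed = 19)
  fit <- fit_pgls_lambda(sim$y, sim$x, tr)
  d <- data.frame(y = sim$y, x = sim$x, sp = names(sim$y))
  ref <- nlme::gls(y ~ x, data = d, method = "ML",
                   correlation = ape::corPagel(0.5, phy = tr, form = ~sp))
  lam_ref <- as.numeric(coef(ref$modelStruct$corStruct,
                             unconstrained = FALSE))
  expect_equal(fit$lambda, lam_ref, tolerance = 1e-3)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-5)
})

test_that("rescaling all branch lengths leaves the fit invariant except sigma2", {
  tr <- random_yule(40, seed = 29)
  sim <- simulate_regression_dataset(tr, slope = 0.4, lam = 0.6,
                                     sigma2 = 1, seed = 29)
  fit1 <- fit_pgls_lambda(sim$y, sim$x, tr)
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 8
  fit2 <- fit_pgls_lambda(sim$y, sim$x, tr2)
  expect_equal(fit2$lambda, fit1$lambda, tolerance = 1e-4)
  expect_equal(fit2$beta, fit1$beta, tolerance = 1e-6)
  expect_equal(fit2$r2, fit1$r2, tolerance = 1e-6)
  expect_equal(fit2$p_slope, fit1$p_slope, tolerance = 1e-6)
  expect_equal(fit2$sigma2, fit1$sigma2 / 8, tolerance = 1e-6)
})

test_that("lambda near zero is recovered from unstructured noise", {
  hits <- 0L
  for (rep in 1:20) {
    tr <- random_yule(100, seed = 400 + rep)
    set.seed(500 + rep)
    x <- setNames(rnorm(100), tr$tip.label)
    y <- setNames(1 + 0.3 * x + rnorm(100), tr$tip.label)
    fit <- fit_pgls_lambda(y, x, tr)
    if (fit$lambda < 0.1) hits <- hits + 1L
  }
  expect_gte(hits, 17L)  # >= 85% of replicates near the true lambda = 0
})

test_that("fixed-lambda fits and data alignment behave as documented", {
  tr <- random_yule(30, seed = 31)
  sim <- simulate_regression_dataset(tr, slope = 0.2, lam = 1,
                                     sigma2 = 1, seed = 31)
  f0 <- fit_pgls_lambda(sim$y, sim$x, tr, lambda = 0)
  f1 <- fit_pgls_lambda(sim$y, sim$x, tr, lambda = 1)
  expect_equal(f0$lambda, 0)
  expect_equal(f1$lambda, 1)
  expect_equal(f0$loglik, f0$loglik_lambda0, tolerance = 1e-10)
  expect_error(fit_pgls_lambda(sim$y, sim$x, tr, lambda = 2), "\\[0, 1\\]")

  # shuffled names give the same fit; pairwise NA dropping re-prunes
  perm <- sample(names(sim$y))
  fit_a <- fit_pgls_lambda(sim$y, sim$x, tr)
  fit_b <- fit_pgls_lambda(sim$y[perm], sim$x[rev(perm)], tr)
  expect_equal(fit_b$beta, fit_a$beta, tolerance = 1e-8)
  y_na <- sim$y; y_na[1:5] <- NA
  fit_c <- fit_pgls_lambda(y_na, sim$x, tr)
  expect_equal(fit_c$n, 25L)

  bad <- setNames(rnorm(30), paste0("zz", 1:30))
  expect_error(fit_pgls_lambda(bad, bad, tr), "no overlap")
  expect_error(fit_pgls_lambda(sim$y[1:3], sim$x[1:3], tr), "at least 4")
  expect_error(fit_pgls_lambda(unname(sim$y), sim$x, tr), "named")
})
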