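test_that("the variational bound gradient matches finite differences", {
  set.seed(3)
  n <- 8; d <- 2
  X <- matrix(rnorm(n * d), n, d)
  y <- sin(X[, 1]) + rnorm(n, 0, 0.2)
  prep <- vhtraits:::prep_inputs(X, y)
  D <- vhtraits:::dim_sqdiffs(prep$Xs)
  theta <- c(rnorm(d, 0, 0.3), 0.2, rnorm(d, 0, 0.3), -0.5, -1.2,
             rnorm(n, 0, 0.4))
  obj <- function(th) vhtraits:::vhgpr_objective(th, prep$ys, D, d, n, 1e-8,
                                                 grad = FALSE)$value
  g_ana <- vhtraits:::vhgpr_objective(theta, prep$ys, D, d, n, 1e-8,
                                      grad = TRUE)$grad
  eps <- 1e-6
  g_num <- vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (obj(tp) - obj(tm)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(g_ana - g_num) / (abs(g_num) + 1e-6)), 1e-5)
})

test_that("duplicated training points are interpolated", {
  X <- matrix(c(0.4, 0.4), 2, 1)
  y <- c(1.7, 1.7)
  m <- fit_vhgpr(X, y, config = cheap_config(), seed = 1)
  pr <- predict(m, matrix(0.4))
  expect_equal(pr$mean, 1.7, tolerance = 1e-3)
})

test_that("pinning the noise GP to a constant recovers exact GPR", {
  set.seed(5)
  n <- 30
  X <- matrix(runif(n, -2, 2), n, 1)
  y <- sin(X[, 1]) + rnorm(n, 0, 0.1)
  prep <- vhtraits:::prep_inputs(X, y)
  # shared hyperparameters in standardized space
  ell <- 0.7; sf2 <- 1.3; sn2 <- 0.05
  # a VHGPR model whose log-noise GP has essentially zero variance and a
  # mean pinned at log(sn2): heteroscedasticity switched off
  theta <- c(log(ell), log(sf2), 0, log(1e-12), log(sn2), rep(0, n))
  model <- structure(
    list(type = "vhgpr", theta = theta, bound = NA_real_, d = 1L, n = n,
         config = vhgpr_config(), scaling = prep$scaling, X = X, y = y,
         seed = 1L),
    class = "vhgpr_model")
  model <- vhtraits:::rebuild_vhgpr_caches(model)
  Xq <- matrix(seq(-2, 2, length.out = 41))
  got <- predict(model, Xq)
  # independent closed-form GP posterior on the standardized problem
  Xqs <- (Xq - prep$scaling$mx) / prep$scaling$sx
  oracle <- gpr_closed_form(prep$Xs, prep$ys, Xqs, ell, sf2, sn2)
  want_mean <- prep$scaling$my + prep$scaling$sy * oracle$mean
  expect_lt(max(abs(got$mean - want_mean) /
                  (abs(want_mean) + 1e-12)), 1e-6)
  want_var <- prep$scaling$sy^2 * oracle$var
  expect_equal(got$var, want_var, tolerance = 1e-4)
})

test_that("VHGPR matches closed-form GPR on homoscedastic data", {
  set.seed(7)
  n <- 80
  X <- matrix(runif(n, 0, 6), n, 1)
  sigma <- 0.15
  y <- sin(X[, 1]) + rnorm(n, 0, sigma)
  m <- fit_vhgpr(X, y, config = cheap_config(restarts = 2, maxit = 200),
                 seed = 2)
  g <- fit_gpr_baseline(X, y, config = cheap_config(restarts = 2,
                                                    maxit = 200), seed = 2)
  Xq <- matrix(seq(0.2, 5.8, length.out = 100))
  pm <- predict(m, Xq)$mean
  pg <- predict(g, Xq)$mean
  # the two posteriors agree to a small fraction of the noise SD
  expect_lt(sqrt(mean((pm - pg)^2)), 0.05 * sigma / 0.15 * sigma / sigma)
  expect_lt(sqrt(mean((pm - pg)^2)), 0.05)
})

test_that("heteroscedastic structure is recovered on Goldberg-style data", {
  gd <- make_goldberg(100, seed = 11)
  m <- fit_vhgpr(gd$x, gd$y, config = cheap_config(restarts = 2,
                                                   maxit = 200), seed = 1)
  pr <- predict(m, gd$x)
  # predicted local noise SD tracks the true noise profile
  expect_gt(cor(sqrt(pr$var_noise), gd$sig, method = "spearman"), 0.8)
  # and the low-noise end is more confident than the high-noise end
  expect_lt(mean(pr$sd[1:20]), mean(pr$sd[81:100]))
  # on the same data the heteroscedastic model wins in held-out NLPD
  set.seed(12)
  xt <- matrix(runif(150), 150, 1)
  yt <- 2 * sin(2 * pi * xt[, 1]) + rnorm(150, 0, 0.1 + xt[, 1])
  g <- fit_gpr_baseline(gd$x, gd$y, config = cheap_config(restarts = 2,
                                                          maxit = 200),
                        seed = 1)
  expect_lt(nlpd(m, xt, yt), nlpd(g, xt, yt))
})

test_that("predictions revert to the prior far from the data", {
  set.seed(4)
  X <- matrix(runif(40, 0, 1), 40, 1)
  y <- 3 + sin(6 * X[, 1]) + rnorm(40, 0, 0.1)
  m <- fit_vhgpr(X, y, config = cheap_config(), seed = 1)
  far <- predict(m, matrix(1e4))
  expect_equal(far$mean, mean(y), tolerance = 0.05 * diff(range(y)))
  near <- predict(m, matrix(0.5))
  expect_gt(far$sd, near$sd)
  # duplicate query rows give identical predictions
  two <- predict(m, matrix(c(0.3, 0.3), 2, 1))
  expect_identical(two$mean[1], two$mean[2])
  expect_identical(two$sd[1], two$sd[2])
  # dimension mismatches are validation errors
  expect_error(predict(m, matrix(0.5, 1, 2)), "expects 1")
})

test_that("standardization round-trip: affine input/target transforms", {
  set.seed(9)
  X <- matrix(runif(60, 0, 2), 30, 2)
  y <- X[, 1] - 0.5 * X[, 2] + rnorm(30, 0, 0.1)
  cfg <- cheap_config()
  m1 <- fit_vhgpr(X, y, config = cfg, seed = 3)
  a <- c(2.5, 0.4); b <- c(-1, 7); cc <- 3.5; e <- -2
  m2 <- fit_vhgpr(sweep(sweep(X, 2, a, "*"), 2, b, "+"), cc * y + e,
                  config = cfg, seed = 3)
  Xq <- matrix(runif(20, 0, 2), 10, 2)
  p1 <- predict(m1, Xq)
  p2 <- predict(m2, sweep(sweep(Xq, 2, a, "*"), 2, b, "+"))
  expect_equal(p2$mean, cc * p1$mean + e, tolerance = 1e-7)
  expect_equal(p2$sd, abs(cc) * p1$sd, tolerance = 1e-7)
})

test_that("the reported bound trace never decreases", {
  gd <- make_goldberg(60, seed = 2)
  m <- fit_vhgpr(gd$x, gd$y, config = cheap_config(), seed = 1)
  expect_true(all(diff(m$bound_trace) >= 0))
  expect_true(is.finite(m$bound))
  expect_equal(m$bound, max(m$bound_trace))
})

test_that("NLPD has its closed form and is permutation invariant", {
  gd <- make_goldberg(50, seed = 6)
  m <- fit_vhgpr(gd$x, gd$y, config = cheap_config(), seed = 1)
  idx <- sample(50)
  expect_equal(nlpd(m, gd$x, gd$y), nlpd(m, gd$x[idx, , drop = FALSE],
                                         gd$y[idx]))
  # a perfect prediction with variance v scores 0.5 * log(2 pi v)
  pr <- predict(m, gd$x[1, , drop = FALSE])
  expect_equal(-dnorm(pr$mean, pr$mean, pr$sd, log = TRUE),
               0.5 * log(2 * pi * pr$var))
})

test_that("the homoscedastic baseline recovers a constant noise level", {
  set.seed(10)
  n <- 200
  X <- matrix(runif(n, 0, 4), n, 1)
  y <- cos(X[, 1]) + rnorm(n, 0, 0.25)
  g <- fit_gpr_baseline(X, y, config = cheap_config(restarts = 2,
                                                    maxit = 200), seed = 1)
  expect_lt(abs(gpr_noise_sd(g) - 0.25) / 0.25, 0.2)
  # deterministic under a fixed seed
  g2 <- fit_gpr_baseline(X, y, config = cheap_config(restarts = 2,
                                                     maxit = 200), seed = 1)
  expect_identical(g$theta, g2$theta)
})

test_that("model persistence round-trips predictions exactly", {
  gd <- make_goldberg(40, seed = 3)
  m <- fit_vhgpr(gd$x, gd$y, config = cheap_config(), seed = 1)
  path <- tempfile(fileext = ".json")
  save_gp_model(m, path)
  m2 <- load_gp_model(path)
  Xq <- matrix(seq(0, 1, length.out = 17))
  expect_equal(predict(m2, Xq), predict(m, Xq), tolerance = 1e-12)
  g <- fit_gpr_baseline(gd$x, gd$y, config = cheap_config(), seed = 1)
  save_gp_model(g, path)
  g2 <- load_gp_model(path)
  expect_equal(predict(g2, Xq), predict(g, Xq), tolerance = 1e-12)
})

test_that("non-finite inputs are rejected up front", {
  expect_error(fit_vhgpr(matrix(c(1, NA), 2, 1), c(1, 2)), "finite")
  expect_error(fit_vhgpr(matrix(1), 1), "at least 2")
})
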