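#' Variational heteroscedastic Gaussian process regression
#'
#' Joint approximate Bayesian inference over a latent signal process
#' `f ~ GP(0, Kf)` and a latent log-noise process `g ~ GP(mu0, Kg)`, with
#' observations `y = f(x) + eps(x)`, `eps(x) ~ N(0, exp(g(x)))`. The
#' marginalized variational bound on the log evidence,
#'
#' \deqn{F = \log N(y \mid 0, K_f + R) - \tfrac14 \mathrm{tr}(\Sigma)
#'        - \mathrm{KL}\big(N(\mu, \Sigma)\,\|\,N(\mu_0 1, K_g)\big),}
#'
#' with `R = diag(exp(mu - diag(Sigma)/2))`, is maximized jointly over the
#' kernel hyperparameters and `n` positive variational parameters
#' `lambda`, which parameterize the optimal Gaussian posterior over `g` as
#' `mu = Kg (lambda - 1/2) + mu0` and `Sigma = (Kg^{-1} + Lambda)^{-1}`.
#' Both processes use anisotropic squared-exponential kernels. Targets are
#' standardized internally; predictions are returned in trait units with
#' the variance decomposed into signal (model) variance and expected
#' heteroscedastic noise.
#'
#' @param X n x d numeric matrix of inputs.
#' @param y numeric targets, length n.
#' @param config a [vhgpr_config] list.
#' @param seed integer seed controlling restart initializations.
#' @return An object of class `vhgpr_model`.
#' @references Lazaro-Gredilla, M. and Titsias, M. (2011), Variational
#'   heteroscedastic Gaussian process regression; Lazaro-Gredilla, M.
#'   et al. (2014) on retrieval applications of the same model.
#' @export
fit_vhgpr <- function(X, y, config = vhgpr_config(), seed = 1L) {
  prep <- prep_inputs(X, y)
  d <- ncol(prep$Xs)
  n <- nrow(prep$Xs)
  if (n < 2) stop("need at least 2 training points", call. = FALSE)
  D <- dim_sqdiffs(prep$Xs)

  init_theta <- function(r) {
    ell_f <- log(pmax(apply(prep$Xs, 2, stats::sd), 1e-3) * sqrt(d))
    th <- c(ell_f, 0, ell_f + log(2), log(0.5), log(0.25), rep(0, n))
    if (r > 1) {
      jit <- stats::rnorm(2 * d + 3, 0, 0.4)
      th[seq_len(2 * d + 3)] <- th[seq_len(2 * d + 3)] + jit
    }
    th
  }
  lower <- c(rep(-8, d), -8, rep(-8, d), -8, -20, rep(-12, n))
  upper <- c(rep(8, d), 8, rep(8, d), 8, 8, rep(12, n))

  best <- NULL
  errors <- character(0)
  with_seed(seed, {
    for (r in seq_len(config$restarts)) {
      theta0 <- init_theta(r)
      tracker <- new.env(parent = emptyenv())
      tracker$trace <- numeric(0)
      fn <- function(th) {
        out <- try(vhgpr_objective(th, prep$ys, D, d, n, config$jitter,
                                   grad = FALSE), silent = TRUE)
        if (inherits(out, "try-error") || !is.finite(out$value)) return(1e10)
        f <- -out$value
        if (!length(tracker$trace) || out$value > max(tracker$trace)) {
          tracker$trace <- c(tracker$trace, out$value)
        }
        f
      }
      gr <- function(th) {
        out <- try(vhgpr_objective(th, prep$ys, D, d, n, config$jitter,
                                   grad = TRUE), silent = TRUE)
        if (inherits(out, "try-error") || !is.finite(out$value)) {
          return(rep(0, length(th)))
        }
        -out$grad
      }
      opt <- try(stats::optim(theta0, fn, gr, method = "L-BFGS-B",
                              lower = lower, upper = upper,
                              control = list(maxit = config$maxit,
                                             factr = config$reltol / 1e-15)),
                 silent = TRUE)
      if (inherits(opt, "try-error")) {
        errors <- c(errors, as.character(opt))
        next
      }
      bound <- -opt$value
      if (is.null(best) || bound > best$bound) {
        best <- list(theta = opt$par, bound = bound, trace = tracker$trace,
                     convergence = opt$convergence)
      }
    }
  })
  if (is.null(best) || !is.finite(best$bound) || best$bound <= -1e9) {
    stop(sprintf(
      "VHGPR optimizer failed after %d restart(s); best bound found: %s",
      config$restarts,
      if (is.null(best)) "none" else format(best$bound)), call. = FALSE)
  }
  model <- structure(
    list(type = "vhgpr", theta = best$theta, bound = best$bound,
         bound_trace = best$trace, d = d, n = n, config = config,
         scaling = prep$scaling, X = prep$X, y = prep$y, seed = seed),
    class = "vhgpr_model")
  rebuild_vhgpr_caches(model)
}

#' Optimizer settings for the GP regressors
#'
#' @param restarts number of multi-start initializations (default 3).
#' @param maxit maximum quasi-Newton iterations per restart (default 500).
#' @param reltol relative bound-change convergence tolerance
#'   (default 1e-6).
#' @param jitter initial diagonal jitter, escalated by factors of 10 up to
#'   1e-4 on factorization failure (default 1e-8).
#' @return A list of class `vhgpr_config`.
#' @export
vhgpr_config <- function(restarts = 3L, maxit = 500L, reltol = 1e-6,
                         jitter = 1e-8) {
  structure(list(restarts = as.integer(restarts), maxit = as.integer(maxit),
                 reltol = reltol, jitter = jitter),
            class = "vhgpr_config")
}

## ---- internals --------------------------------------------------------------

prep_inputs <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y sizes differ", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  mx <- colMeans(X)
  sx <- apply(X, 2, stats::sd)
  sx[!is.finite(sx) | sx < 1e-12] <- 1
  my <- mean(y)
  sy <- stats::sd(y)
  if (!is.finite(sy) || sy < 1e-12) sy <- 1
  Xs <- sweep(sweep(X, 2, mx), 2, sx, "/")
  list(X = X, y = y, Xs = Xs, ys = (y - my) / sy,
       scaling = list(mx = mx, sx = sx, my = my, sy = sy))
}

# per-dimension squared differences, reused across kernel evaluations
dim_sqdiffs <- function(Xs) {
  lapply(seq_len(ncol(Xs)), function(j) outer(Xs[, j], Xs[, j], "-")^2)
}

kernel_from_sqdiffs <- function(D, log_ell, log_s2) {
  ell2 <- exp(2 * log_ell)
  q <- 0
  for (j in seq_along(D)) q <- q + D[[j]] / ell2[j]
  exp(log_s2) * exp(-0.5 * q)
}

chol_jittered <- function(K, jitter0) {
  jit <- jitter0
  repeat {
    L <- try(chol(K + diag(jit, nrow(K))), silent = TRUE)
    if (!inherits(L, "try-error")) return(L)
    jit <- jit * 10
    if (jit > 1e-4 * max(diag(K)) + 1e-4) {
      stop("kernel factorization failed even with escalated jitter",
           call. = FALSE)
    }
  }
}

unpack_theta <- function(theta, d, n) {
  list(lf = theta[1:d], sf2 = theta[d + 1],
       lg = theta[(d + 2):(2 * d + 1)], sg2 = theta[2 * d + 2],
       mu0 = theta[2 * d + 3],
       loglam = theta[(2 * d + 4):(2 * d + 3 + n)])
}

# Marginalized variational bound and (optionally) its analytic gradient.
vhgpr_objective <- function(theta, ys, D, d, n, jitter, grad = TRUE) {
  p <- unpack_theta(theta, d, n)
  lambda <- exp(p$loglam)
  Kf <- kernel_from_sqdiffs(D, p$lf, p$sf2)
  Kg <- kernel_from_sqdiffs(D, p$lg, p$sg2)

  W <- sqrt(lambda)
  Bg <- diag(n) + outer(W, W) * Kg
  Lg <- chol_jittered(Bg, 0)
  Bginv <- chol2inv(Lg)
  KgW <- sweep(Kg, 2, W, "*")               # Kg %*% diag(W)
  Sigma <- Kg - KgW %*% Bginv %*% t(KgW)
  s <- diag(Sigma)
  cc <- lambda - 0.5
  Kgc <- as.vector(Kg %*% cc)
  mu <- Kgc + p$mu0

  expo <- pmin(pmax(mu - s / 2, -35), 35)
  r <- exp(expo)
  B <- Kf + diag(r)
  Lf <- chol_jittered(B, jitter)
  beta <- backsolve(Lf, backsolve(Lf, ys, transpose = TRUE))
  Binv <- chol2inv(Lf)

  F1 <- -0.5 * sum(ys * beta) - sum(log(diag(Lf))) - n / 2 * log(2 * pi)
  F2 <- -0.25 * sum(s)
  KL <- 0.5 * (sum(diag(Bginv)) + sum(cc * Kgc) +
                 2 * sum(log(diag(Lg))) - n)
  value <- F1 + F2 - KL
  if (!grad) return(list(value = value))

  h <- 0.5 * (beta^2 - diag(Binv))
  u <- h * r
  # M = (I + Lambda Kg)^{-1} = I - diag(W) Bginv diag(W) Kg
  T1 <- Bginv %*% sweep(Kg, 1, W, "*")
  M <- diag(n) - sweep(T1, 1, W, "*")

  # variational parameters (chain rule to log lambda)
  Sig2 <- Sigma * Sigma
  g_lam <- as.vector(Kg %*% (u - cc)) +
    as.vector(Sig2 %*% (0.5 * u + 0.25 - 0.5 * lambda))
  g_loglam <- g_lam * lambda

  g_mu0 <- sum(u)

  # signal-kernel hyperparameters
  Q <- tcrossprod(beta) - Binv
  ellf2 <- exp(2 * p$lf)
  g_lf <- vapply(seq_len(d), function(j)
    0.5 * sum(Q * (Kf * D[[j]])) / ellf2[j], numeric(1))
  g_sf2 <- 0.5 * sum(Q * Kf)

  # noise-kernel hyperparameters via dF = sum(G * dKg)
  MMt <- tcrossprod(M)
  MM <- M %*% M
  G <- outer(u, cc) - 0.5 * (sweep(M, 2, u, "*") %*% t(M)) - 0.25 * MMt +
    0.5 * sweep(t(MM), 1, lambda, "*") - 0.5 * sweep(t(M), 1, lambda, "*") -
    0.5 * outer(cc, cc)
  ellg2 <- exp(2 * p$lg)
  g_lg <- vapply(seq_len(d), function(j)
    sum(G * (Kg * D[[j]])) / ellg2[j], numeric(1))
  g_sg2 <- sum(G * Kg)

  list(value = value,
       grad = c(g_lf, g_sf2, g_lg, g_sg2, g_mu0, g_loglam))
}

# recompute the prediction caches from theta + training data
rebuild_vhgpr_caches <- function(model) {
  prep <- prep_inputs(model$X, model$y)
  D <- dim_sqdiffs(prep$Xs)
  p <- unpack_theta(model$theta, model$d, model$n)
  lambda <- exp(p$loglam)
  Kf <- kernel_from_sqdiffs(D, p$lf, p$sf2)
  Kg <- kernel_from_sqdiffs(D, p$lg, p$sg2)
  W <- sqrt(lambda)
  Bg <- diag(model$n) + outer(W, W) * Kg
  Lg <- chol_jittered(Bg, 0)
  Bginv <- chol2inv(Lg)
  KgW <- sweep(Kg, 2, W, "*")
  s <- diag(Kg) - rowSums((KgW %*% Bginv) * KgW)
  cc <- lambda - 0.5
  mu <- as.vector(Kg %*% cc) + p$mu0
  r <- exp(pmin(pmax(mu - s / 2, -35), 35))
  B <- Kf + diag(r)
  Lf <- chol_jittered(B, model$config$jitter)
  model$cache <- list(
    Xs = prep$Xs, params = p, lambda = lambda,
    beta = backsolve(Lf, backsolve(Lf, prep$ys, transpose = TRUE)),
    Binv = chol2inv(Lf),
    Vg = sweep(sweep(Bginv, 1, W, "*"), 2, W, "*"),  # (Kg + Lambda^-1)^-1
    cc = cc)
  model
}

cross_kernel <- function(Xq, Xs, log_ell, log_s2) {
  ell <- exp(log_ell)
  q <- 0
  for (j in seq_len(ncol(Xs))) {
    q <- q + outer(Xq[, j], Xs[, j], "-")^2 / ell[j]^2
  }
  exp(log_s2) * exp(-0.5 * q)
}

# Per-row linear form ks %*% w and quadratic form diag(ks A ks'): computed
# row by row so every prediction depends only on its own query row. This
# keeps mapping results bit-identical under any tiling of an image (batched
# matrix products may differ in the last ulp between batch shapes).
rowwise_linear <- function(ks, w) {
  rowSums(sweep(ks, 2, w, "*"))
}

rowwise_quad <- function(ks, A) {
  vapply(seq_len(nrow(ks)), function(i) {
    v <- ks[i, ]
    sum(v * as.vector(A %*% v))
  }, numeric(1))
}

#' Predict from a fitted heteroscedastic GP model
#'
#' Closed-form predictive mean and variance at query inputs. The total
#' variance is the posterior variance of the signal process plus the
#' expected heteroscedastic noise variance
#' `E[exp(g*)] = exp(mu_g* + var_g*/2)`; both parts are reported,
#' destandardized to trait units. The coefficient of variation `sd/mean`
#' is reported only where `|mean|` exceeds `1e-6`.
#'
#' @param object a `vhgpr_model`.
#' @param Xq m x d matrix of query inputs.
#' @param ... unused.
#' @return A data.frame with columns `mean`, `var`, `sd`, `var_model`,
#'   `var_noise`, `cv`.
#' @export
predict.vhgpr_model <- function(object, Xq, ...) {
  Xq <- as.matrix(Xq)
  if (ncol(Xq) != object$d) {
    stop(sprintf("query has %d columns, model expects %d", ncol(Xq),
                 object$d), call. = FALSE)
  }
  if (any(!is.finite(Xq))) stop("query inputs must be finite", call. = FALSE)
  sc <- object$scaling
  Xqs <- sweep(sweep(Xq, 2, sc$mx), 2, sc$sx, "/")
  ca <- object$cache
  p <- ca$params

  ksf <- cross_kernel(Xqs, ca$Xs, p$lf, p$sf2)
  mf <- rowwise_linear(ksf, ca$beta)
  vf <- pmax(exp(p$sf2) - rowwise_quad(ksf, ca$Binv), 1e-12)

  ksg <- cross_kernel(Xqs, ca$Xs, p$lg, p$sg2)
  mg <- rowwise_linear(ksg, ca$cc) + p$mu0
  vg <- pmax(exp(p$sg2) - rowwise_quad(ksg, ca$Vg), 0)
  vnoise <- exp(pmin(mg + vg / 2, 35))

  finish_prediction(mf, vf, vnoise, sc)
}

finish_prediction <- function(mf, vf, vnoise, sc) {
  mean_out <- sc$my + sc$sy * mf
  var_model <- sc$sy^2 * vf
  var_noise <- sc$sy^2 * vnoise
  v <- var_model + var_noise
  sd_out <- sqrt(v)
  cv <- ifelse(abs(mean_out) > 1e-6, sd_out / mean_out, NA_real_)
  data.frame(mean = mean_out, var = v, sd = sd_out,
             var_model = var_model, var_noise = var_noise, cv = cv)
}

#' Mean negative log predictive density
#'
#' Average of `-log N(y | mean, var)` over evaluation rows, using each
#' model's total predictive variance. Lower is better; heteroscedastic
#' models are rewarded for matching local noise levels.
#'
#' @param model a fitted `vhgpr_model` or `gpr_model`.
#' @param X evaluation inputs.
#' @param y evaluation targets.
#' @return Scalar mean NLPD.
#' @export
nlpd <- function(model, X, y) {
  pr <- stats::predict(model, X)
  v <- pmax(pr$var, 1e-12)
  -mean(stats::dnorm(y, pr$mean, sqrt(v), log = TRUE))
}

## ---- homoscedastic GPR baseline ---------------------------------------------

#' Standard (homoscedastic) Gaussian process regression baseline
#'
#' Exact GP regression with an anisotropic squared-exponential kernel and a
#' single constant noise variance, fitted by marginal-likelihood
#' maximization. Serves as the constant-noise reference the
#' heteroscedastic model is compared against.
#'
#' @inheritParams fit_vhgpr
#' @return An object of class `gpr_model`.
#' @export
fit_gpr_baseline <- function(X, y, config = vhgpr_config(), seed = 1L) {
  prep <- prep_inputs(X, y)
  d <- ncol(prep$Xs)
  n <- nrow(prep$Xs)
  if (n < 2) stop("need at least 2 training points", call. = FALSE)
  D <- dim_sqdiffs(prep$Xs)
  ys <- prep$ys

  objective <- function(theta) {
    lf <- theta[1:d]; sf2 <- theta[d + 1]; sn2 <- theta[d + 2]
    K <- kernel_from_sqdiffs(D, lf, sf2)
    Ky <- K + diag(exp(sn2) + config$jitter, n)
    L <- chol_jittered(Ky, 0)
    alpha <- backsolve(L, backsolve(L, ys, transpose = TRUE))
    nll <- 0.5 * sum(ys * alpha) + sum(log(diag(L))) + n / 2 * log(2 * pi)
    Kinv <- chol2inv(L)
    Q <- tcrossprod(alpha) - Kinv
    ell2 <- exp(2 * lf)
    g_lf <- vapply(seq_len(d), function(j)
      -0.5 * sum(Q * (K * D[[j]])) / ell2[j], numeric(1))
    g_sf2 <- -0.5 * sum(Q * K)
    g_sn2 <- -0.5 * sum(diag(Q)) * exp(sn2)
    list(value = nll, grad = c(g_lf, g_sf2, g_sn2))
  }

  init_theta <- function(r) {
    th <- c(log(pmax(apply(prep$Xs, 2, stats::sd), 1e-3) * sqrt(d)), 0,
            log(0.1))
    if (r > 1) th <- th + stats::rnorm(length(th), 0, 0.4)
    th
  }

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(config$restarts)) {
      fn <- function(th) {
        out <- try(objective(th), silent = TRUE)
        if (inherits(out, "try-error") || !is.finite(out$value)) return(1e10)
        out$value
      }
      gr <- function(th) {
        out <- try(objective(th), silent = TRUE)
        if (inherits(out, "try-error") || !is.finite(out$value)) {
          return(rep(0, length(th)))
        }
        out$grad
      }
      opt <- try(stats::optim(init_theta(r), fn, gr, method = "L-BFGS-B",
                              lower = rep(-10, d + 2),
                              upper = rep(10, d + 2),
                              control = list(maxit = config$maxit,
                                             factr = config$reltol / 1e-15)),
                 silent = TRUE)
      if (inherits(opt, "try-error")) next
      if (is.null(best) || opt$value < best$nll) {
        best <- list(theta = opt$par, nll = opt$value)
      }
    }
  })
  if (is.null(best)) stop("GPR optimizer failed in all restarts",
                          call. = FALSE)
  model <- structure(
    list(type = "gpr", theta = best$theta, nll = best$nll, d = d, n = n,
         config = config, scaling = prep$scaling, X = prep$X, y = prep$y,
         seed = seed),
    class = "gpr_model")
  rebuild_gpr_caches(model)
}

rebuild_gpr_caches <- function(model) {
  prep <- prep_inputs(model$X, model$y)
  D <- dim_sqdiffs(prep$Xs)
  d <- model$d
  lf <- model$theta[1:d]; sf2 <- model$theta[d + 1]
  sn2 <- exp(model$theta[d + 2])
  K <- kernel_from_sqdiffs(D, lf, sf2)
  L <- chol_jittered(K + diag(sn2 + model$config$jitter, model$n), 0)
  model$cache <- list(
    Xs = prep$Xs, lf = lf, sf2 = sf2, sn2 = sn2,
    alpha = backsolve(L, backsolve(L, prep$ys, transpose = TRUE)),
    Kinv = chol2inv(L))
  model
}

#' @rdname fit_gpr_baseline
#' @param object a `gpr_model`.
#' @param Xq m x d query matrix.
#' @param ... unused.
#' @export
predict.gpr_model <- function(object, Xq, ...) {
  Xq <- as.matrix(Xq)
  if (ncol(Xq) != object$d) {
    stop(sprintf("query has %d columns, model expects %d", ncol(Xq),
                 object$d), call. = FALSE)
  }
  sc <- object$scaling
  Xqs <- sweep(sweep(Xq, 2, sc$mx), 2, sc$sx, "/")
  ca <- object$cache
  ks <- cross_kernel(Xqs, ca$Xs, ca$lf, ca$sf2)
  mf <- rowwise_linear(ks, ca$alpha)
  vf <- pmax(exp(ca$sf2) - rowwise_quad(ks, ca$Kinv), 1e-12)
  finish_prediction(mf, vf, rep(ca$sn2, length(mf)), sc)
}

#' Fitted constant noise standard deviation of the GPR baseline
#' @param model a `gpr_model`.
#' @return Noise SD in target units.
#' @export
gpr_noise_sd <- function(model) {
  model$scaling$sy * sqrt(exp(model$theta[model$d + 2]))
}

## ---- persistence ------------------------------------------------------------

#' Save / load a fitted GP model as self-describing JSON
#'
#' The file carries a format version, model type, kernel name, all
#' hyperparameters and variational parameters, standardization constants
#' and an embedded copy of the training data; prediction caches are
#' rebuilt on load, so the round-trip reproduces predictions exactly.
#'
#' @param model a `vhgpr_model` or `gpr_model`.
#' @param path file path (JSON).
#' @return `save_gp_model` returns `path` invisibly; `load_gp_model` the
#'   reconstructed model.
#' @export
save_gp_model <- function(model, path) {
  stopifnot(inherits(model, c("vhgpr_model", "gpr_model")))
  payload <- list(
    format = "vhtraits-gp/1", type = model$type,
    kernel = "squared-exponential-ard",
    theta = model$theta, d = model$d, n = model$n,
    config = unclass(model$config), scaling = model$scaling,
    X = model$X, y = model$y, seed = model$seed,
    bound = model$bound %||% NULL, nll = model$nll %||% NULL)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_gp_model
#' @export
load_gp_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "vhtraits-gp/1")) {
    stop("unrecognized model file format", call. = FALSE)
  }
  config <- structure(p$config, class = "vhgpr_config")
  base <- list(type = p$type, theta = p$theta, d = p$d, n = p$n,
               config = config,
               scaling = lapply(p$scaling, as.numeric),
               X = matrix(unlist(p$X), nrow = p$n), y = p$y, seed = p$seed)
  if (p$type == "vhgpr") {
    base$bound <- p$bound
    model <- structure(base, class = "vhgpr_model")
    rebuild_vhgpr_caches(model)
  } else {
    base$nll <- p$nll
    model <- structure(base, class = "gpr_model")
    rebuild_gpr_caches(model)
  }
}
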