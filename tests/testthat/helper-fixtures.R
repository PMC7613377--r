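# Shared fixtures built in code at test time.

# small cheap optimizer settings for unit tests
cheap_config <- function(restarts = 1L, maxit = 80L) {
  vhgpr_config(restarts = restarts, maxit = maxit)
}

# Goldberg-style heteroscedastic 1-d regression data: smooth signal with a
# noise SD that grows linearly in x.
make_goldberg <- function(n, seed) {
  set.seed(seed)
  x <- matrix(sort(stats::runif(n)), n, 1)
  sig <- 0.1 + x[, 1]
  y <- 2 * sin(2 * pi * x[, 1]) + stats::rnorm(n, 0, sig)
  list(x = x, y = y, sig = sig)
}

# closed-form homoscedastic GP posterior mean/variance (independent oracle)
gpr_closed_form <- function(X, y, Xq, ell, sf2, sn2) {
  X <- as.matrix(X); Xq <- as.matrix(Xq)
  sqd <- function(A, B) {
    out <- 0
    for (j in seq_len(ncol(A))) {
      out <- out + outer(A[, j], B[, j], "-")^2 / ell[j]^2
    }
    out
  }
  K <- sf2 * exp(-0.5 * sqd(X, X)) + diag(sn2, nrow(X))
  ks <- sf2 * exp(-0.5 * sqd(Xq, X))
  Kinv <- solve(K)
  list(mean = as.vector(ks %*% Kinv %*% y),
       var = sf2 - rowSums((ks %*% Kinv) * ks) + sn2)
}

# identity-atmosphere LUT (transparent atmosphere) covering the default
# atmospheric sampling ranges, written to a temp file
write_identity_lut <- function(grid = seq(400, 2500, by = 50)) {
  corners <- expand.grid(O3C = c(0.2, 0.4), CWV = c(0.3, 5),
                         AOT = c(0.01, 0.6), ALPHA = c(0.01, 2.1),
                         G = c(0.5, 0.9999))
  states <- lapply(seq_len(nrow(corners)), function(i) {
    do.call(atmosphere_state, c(as.list(corners[i, ]), list(theta_il = 25)))
  })
  ident <- transfer_functions(grid, rho0 = rep(0, length(grid)),
                              tgas = rep(1, length(grid)),
                              tdwn = rep(1, length(grid)),
                              tup = rep(1, length(grid)),
                              s = rep(0, length(grid)),
                              i0 = rep(pi, length(grid)))
  path <- tempfile(fileext = ".csv")
  write_atmosphere_lut(states, rep(list(ident), length(states)), path)
  path
}
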