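test_that("goodness-of-fit statistics follow their definitions", {
  g <- goodness_of_fit(0:3, 1:4)
  expect_equal(g$rmse, 1)
  expect_equal(g$nrmse, 100 / 3, tolerance = 1e-12)
  expect_equal(g$r2, 1 - 4 / sum((0:3 - 1.5)^2))
  # scale invariance of NRMSE and R2; RMSE scales
  g10 <- goodness_of_fit(10 * (0:3), 10 * (1:4))
  expect_equal(g10$nrmse, g$nrmse)
  expect_equal(g10$r2, g$r2)
  expect_equal(g10$rmse, 10 * g$rmse)
  expect_error(goodness_of_fit(c(2, 2, 2), c(1, 2, 3)), "range is zero")
})

test_that("cross-validation folds partition the rows and pool predictions", {
  db <- augment_nonveg(build_boa_db(n = 40, seed = 8), 10, seed = 8)
  # an oracle regressor that memorizes the mapping achieves perfect scores
  oracle <- function(Xtr, ytr, Xte) {
    key <- apply(Xte, 1, paste, collapse = "|")
    full_key <- apply(db$X, 1, paste, collapse = "|")
    db$Y$LAI[match(key, full_key)]
  }
  rep <- kfold_cv(db, k = 5, seed = 2, regressor = oracle, traits = "LAI")
  expect_equal(rep$rmse, 0)
  expect_equal(rep$nrmse, 0)
  expect_equal(rep$r2, 1)
  folds <- attr(rep, "folds")
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(length(folds), 50)
  expect_true(all(table(folds) %in% c(10, 10)))
  # fold assignment is stable under the seed
  rep2 <- kfold_cv(db, k = 5, seed = 2, regressor = oracle, traits = "LAI")
  expect_identical(attr(rep, "folds"), attr(rep2, "folds"))
  # a constant-mean regressor cannot beat R2 = 0
  const_reg <- function(Xtr, ytr, Xte) rep(mean(ytr), nrow(Xte))
  rep_c <- kfold_cv(db, k = 5, seed = 2, regressor = const_reg,
                    traits = "LAI")
  expect_lte(rep_c$r2, 0.05)
  expect_error(kfold_cv(db, k = 51, seed = 1), "exceeds")
  expect_error(kfold_cv(db, k = 5, traits = "nope"), "nope")
})

test_that("per-trait models fit their own columns on clean surrogate data", {
  zero_noise <- list(AD = 0, AI = 0, MD = 0, MI = 0)
  db <- build_boa_db(n = 120, seed = 14, noise = zero_noise)
  bundle <- train_trait_models(db, config = cheap_config(restarts = 2,
                                                         maxit = 200),
                               seed = 1)
  expect_length(bundle$models, 6)
  expect_equal(bundle$meta$scale, "BOA")
  for (tr in bundle$traits) {
    pr <- predict(bundle$models[[tr]], db$X)
    g <- goodness_of_fit(db$Y[[tr]], pr$mean)
    # LAI saturates spectrally above ~5 m2/m2, so even the noiseless
    # inverse mapping is ambiguous there and its in-sample R2 plateaus
    # below that of the other traits
    expect_gt(g$r2, if (tr == "LAI") 0.8 else 0.9)
  }
  expect_error(train_trait_models(db, traits = "missing"), "missing")
})

test_that("trait model bundles round-trip through serialization", {
  db <- build_boa_db(n = 25, seed = 15)
  bundle <- train_trait_models(db, traits = c("LAI", "FVC"),
                               config = cheap_config(), seed = 1)
  path <- tempfile(fileext = ".json")
  save_bundle(bundle, path)
  back <- load_bundle(path)
  expect_equal(back$meta$scale, "BOA")
  expect_equal(back$traits, c("LAI", "FVC"))
  Xq <- db$X[1:5, ]
  for (tr in back$traits) {
    expect_equal(predict(back$models[[tr]], Xq),
                 predict(bundle$models[[tr]], Xq), tolerance = 1e-12)
  }
})

test_that("mapping handles masking, chunking and band mismatches", {
  db <- build_boa_db(n = 30, seed = 16)
  bundle <- train_trait_models(db, traits = c("LAI", "Cab"),
                               config = cheap_config(), seed = 1)
  # a constant image maps to spatially constant traits
  px <- db$X[7, ]
  arr <- array(rep(px, each = 12), c(3, 4, 10))
  maps <- map_image(arr, bundle)
  expect_equal(max(maps$maps$LAI$mean) - min(maps$maps$LAI$mean), 0)
  expect_equal(maps$masked, 0)
  # chunked and unchunked processing are bit-identical
  set.seed(20)
  arr2 <- array(pmin(pmax(rep(db$X[sample(30, 24, TRUE), ], 1), 0), 1),
                c(6, 4, 10))
  m_all <- map_image(arr2, bundle, chunk_size = 1e6)
  m_chunk <- map_image(arr2, bundle, chunk_size = 5)
  expect_identical(m_all$maps$LAI$mean, m_chunk$maps$LAI$mean)
  expect_identical(m_all$maps$Cab$sd, m_chunk$maps$Cab$sd)
  # invalid pixels are masked and counted
  arr2[1, 1, 3] <- 3.2
  arr2[2, 2, 1] <- NA
  m_bad <- map_image(arr2, bundle)
  expect_equal(m_bad$masked, 2)
  expect_true(is.na(m_bad$maps$LAI$mean[1, 1]))
  expect_true(is.na(m_bad$maps$LAI$cv[2, 2]))
  # band count mismatch is a configuration error
  expect_error(map_image(array(0.2, c(3, 4, 9)), bundle), "9 bands")
})

test_that("map comparison statistics and relative errors are exact", {
  set.seed(31)
  A <- matrix(runif(100, 1, 5), 10, 10)
  self <- compare_maps(A, A)
  expect_equal(self$stats$r2, 1)
  expect_equal(self$stats$rmse, 0)
  expect_true(all(self$relative_error == 0))
  dbl <- compare_maps(A, 2 * A)
  expect_true(all(abs(dbl$relative_error + 0.5) < 1e-12))
  expect_error(compare_maps(A, matrix(1, 5, 5)), "different grids")
  # masking: tiny denominators are excluded from the relative error
  B <- A
  B[1, 1] <- 0
  cmp <- compare_maps(A, B)
  expect_true(is.na(cmp$relative_error[1, 1]))
})

test_that("uncertainty masking blanks all layers of the trait", {
  db <- build_boa_db(n = 25, seed = 17)
  bundle <- train_trait_models(db, traits = "LAI",
                               config = cheap_config(), seed = 1)
  arr <- array(rep(db$X[3, ], each = 4), c(2, 2, 10))
  maps <- map_image(arr, bundle)
  masked <- mask_by_uncertainty(maps, "LAI", -1, type = "sd")
  expect_true(all(is.na(masked$maps$LAI$mean)))
  kept <- mask_by_uncertainty(maps, "LAI", Inf, type = "sd")
  expect_identical(kept$maps$LAI$mean, maps$maps$LAI$mean)
})
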