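#' Goodness-of-fit statistics for retrieval validation
#'
#' Root mean squared error in trait units, normalized RMSE in percent
#' (`100 * RMSE / (max(obs) - min(obs))`, the range of the observation
#' vector supplied), and the coefficient of determination
#' `R2 = 1 - SSE/SST` (which can be negative for models worse than the
#' observation mean).
#'
#' @param obs observed values.
#' @param pred predicted values, same length.
#' @return A list with `rmse`, `nrmse` (%), `r2`, `n`, `range`.
#' @export
goodness_of_fit <- function(obs, pred) {
  obs <- as.numeric(obs); pred <- as.numeric(pred)
  if (length(obs) != length(pred) || length(obs) < 2) {
    stop("obs and pred must be equal-length vectors of length >= 2",
         call. = FALSE)
  }
  if (any(!is.finite(obs)) || any(!is.finite(pred))) {
    stop("obs and pred must be finite", call. = FALSE)
  }
  rng <- range(obs)
  if (diff(rng) <= 0) {
    stop("observation range is zero; NRMSE undefined", call. = FALSE)
  }
  sse <- sum((obs - pred)^2)
  sst <- sum((obs - mean(obs))^2)
  rmse <- sqrt(sse / length(obs))
  list(rmse = rmse, nrmse = 100 * rmse / diff(rng), r2 = 1 - sse / sst,
       n = length(obs), range = rng)
}

resolve_regressor <- function(regressor, config, seed) {
  if (is.function(regressor)) return(regressor)
  if (identical(regressor, "vhgpr")) {
    return(function(Xtr, ytr, Xte) {
      m <- fit_vhgpr(Xtr, ytr, config = config, seed = seed)
      stats::predict(m, Xte)$mean
    })
  }
  if (identical(regressor, "gpr")) {
    return(function(Xtr, ytr, Xte) {
      m <- fit_gpr_baseline(Xtr, ytr, config = config, seed = seed)
      stats::predict(m, Xte)$mean
    })
  }
  stop("regressor must be 'vhgpr', 'gpr' or a function(Xtr, ytr, Xte)",
       call. = FALSE)
}

#' k-fold cross-validation of per-trait retrieval models
#'
#' Rows are partitioned into `k` folds (each row held out exactly once);
#' per trait an independent model is trained on the remaining folds and
#' applied to the held-out rows; statistics are computed on the pooled
#' out-of-fold predictions.
#'
#' @param db a [training_db].
#' @param k number of folds (default 5).
#' @param seed integer seed (fold assignment and model fits).
#' @param regressor `"vhgpr"` (default), `"gpr"`, or a function
#'   `(Xtr, ytr, Xte) -> predictions` (e.g. an oracle in tests).
#' @param traits trait columns to evaluate (default all six).
#' @param config [vhgpr_config] passed to the built-in regressors.
#' @return A data.frame of class `gof_report`: one row per trait with
#'   `rmse`, `nrmse` (%), `r2`, `n`, `range_lo`, `range_hi`, plus the
#'   pooled predictions in `attr(, "predictions")`.
#' @export
kfold_cv <- function(db, k = 5, seed = 1L, regressor = "vhgpr",
                     traits = trait_names, config = vhgpr_config()) {
  stopifnot(inherits(db, "training_db"))
  n <- nrow(db$X)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop(sprintf("k = %d exceeds the %d database rows", k, n),
                  call. = FALSE)
  missing_tr <- setdiff(traits, names(db$Y))
  if (length(missing_tr)) {
    stop("traits not in the database: ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  }
  folds <- with_seed(derive_seed(seed, "folds"),
                     sample(rep(seq_len(k), length.out = n)))
  reg <- resolve_regressor(regressor, config, derive_seed(seed, "fit"))
  preds <- matrix(NA_real_, n, length(traits),
                  dimnames = list(NULL, traits))
  for (fold in seq_len(k)) {
    te <- folds == fold
    for (tr in traits) {
      preds[te, tr] <- reg(db$X[!te, , drop = FALSE], db$Y[[tr]][!te],
                           db$X[te, , drop = FALSE])
    }
  }
  rows <- lapply(traits, function(tr) {
    g <- goodness_of_fit(db$Y[[tr]], preds[, tr])
    data.frame(trait = tr, rmse = g$rmse, nrmse = g$nrmse, r2 = g$r2,
               n = g$n, range_lo = g$range[1], range_hi = g$range[2])
  })
  out <- do.call(rbind, rows)
  attr(out, "predictions") <- preds
  attr(out, "folds") <- folds
  class(out) <- c("gof_report", class(out))
  out
}

#' Train one retrieval model per trait on a database
#'
#' Fits an independent VHGPR model per requested trait, all sharing the
#' band-reflectance inputs; the bundle keeps the database metadata (scale
#' tag, band centres) so mapping can verify band compatibility.
#'
#' @param db a [training_db].
#' @param traits traits to model (default all six).
#' @param config [vhgpr_config].
#' @param seed integer seed.
#' @param regressor `"vhgpr"` (default) or `"gpr"`.
#' @return An object of class `trait_model_bundle`.
#' @export
train_trait_models <- function(db, traits = trait_names,
                               config = vhgpr_config(), seed = 1L,
                               regressor = "vhgpr") {
  stopifnot(inherits(db, "training_db"))
  missing_tr <- setdiff(traits, names(db$Y))
  if (length(missing_tr)) {
    stop("traits not in the database: ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  }
  fit_fun <- if (identical(regressor, "gpr")) fit_gpr_baseline else fit_vhgpr
  models <- lapply(traits, function(tr) {
    fit_fun(db$X, db$Y[[tr]], config = config,
            seed = derive_seed(seed, "fit"))
  })
  names(models) <- traits
  structure(list(models = models, traits = traits,
                 meta = db$meta[c("scale", "band_names", "bands", "seed",
                                  "provider")]),
            class = "trait_model_bundle")
}

#' @export
print.trait_model_bundle <- function(x, ...) {
  cat(sprintf("<trait_model_bundle: %s scale, traits: %s>\n",
              x$meta$scale, paste(x$traits, collapse = ", ")))
  invisible(x)
}

#' Save / load a trait model bundle (JSON)
#' @param bundle a `trait_model_bundle`.
#' @param path file path.
#' @return `save_bundle` returns `path` invisibly; `load_bundle` the bundle.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "trait_model_bundle"))
  payload <- list(
    format = "vhtraits-bundle/1", meta = bundle$meta, traits = bundle$traits,
    models = lapply(bundle$models, function(m) {
      list(type = m$type, theta = m$theta, d = m$d, n = m$n,
           config = unclass(m$config), scaling = m$scaling, X = m$X,
           y = m$y, seed = m$seed, bound = m$bound %||% NULL,
           nll = m$nll %||% NULL)
    }))
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "vhtraits-bundle/1")) {
    stop("unrecognized bundle file format", call. = FALSE)
  }
  models <- lapply(p$models, function(m) {
    base <- list(type = m$type, theta = m$theta, d = m$d, n = m$n,
                 config = structure(m$config, class = "vhgpr_config"),
                 scaling = lapply(m$scaling, as.numeric),
                 X = matrix(unlist(m$X), nrow = m$n), y = m$y,
                 seed = m$seed)
    if (m$type == "vhgpr") {
      base$bound <- m$bound
      rebuild_vhgpr_caches(structure(base, class = "vhgpr_model"))
    } else {
      base$nll <- m$nll
      rebuild_gpr_caches(structure(base, class = "gpr_model"))
    }
  })
  names(models) <- p$traits
  meta <- as.list(p$meta)
  structure(list(models = models, traits = p$traits, meta = meta),
            class = "trait_model_bundle")
}

#' Map traits and uncertainties over a multiband raster
#'
#' Applies each trait model per pixel, producing mean, SD and CV layers.
#' Pixels with any non-finite band or any reflectance outside
#' `[-0.01, 1.1]` are masked (`NA` in all layers); the number of masked
#' pixels is reported in the result's `masked` field. Processing is
#' chunked by rows of pixels; any chunking yields identical maps.
#'
#' @param raster numeric array `rows x cols x bands` (reflectance
#'   fractions), or a list from [read_raster].
#' @param bundle a `trait_model_bundle` whose band count matches.
#' @param chunk_size pixels per prediction chunk (default 4096).
#' @return An object of class `trait_maps`: per trait a list of `mean`,
#'   `sd`, `cv` matrices, plus `geo` metadata and `masked` count.
#' @export
map_image <- function(raster, bundle, chunk_size = 4096) {
  stopifnot(inherits(bundle, "trait_model_bundle"))
  geo <- NULL
  if (is.list(raster) && !is.null(raster$array)) {
    geo <- raster$geo
    raster <- raster$array
  }
  if (length(dim(raster)) != 3L) {
    stop("raster must be a rows x cols x bands array", call. = FALSE)
  }
  nb <- dim(raster)[3]
  want <- length(bundle$meta$band_names)
  if (nb != want) {
    stop(sprintf("raster has %d bands but the bundle expects %d (%s)",
                 nb, want, paste(bundle$meta$band_names, collapse = ", ")),
         call. = FALSE)
  }
  nr <- dim(raster)[1]; nc <- dim(raster)[2]
  Xpix <- matrix(raster, nr * nc, nb)  # pixel-major, column-major over rows
  valid <- rowSums(!is.finite(Xpix)) == 0 &
    rowSums(Xpix < -0.01 | Xpix > 1.1, na.rm = TRUE) == 0
  idx <- which(valid)
  out <- lapply(bundle$traits, function(tr) {
    m <- matrix(NA_real_, nr, nc)
    list(mean = m, sd = m, cv = m)
  })
  names(out) <- bundle$traits
  if (length(idx)) {
    starts <- seq(1L, length(idx), by = chunk_size)
    for (s in starts) {
      rows <- idx[s:min(s + chunk_size - 1L, length(idx))]
      Xc <- Xpix[rows, , drop = FALSE]
      for (tr in bundle$traits) {
        pr <- stats::predict(bundle$models[[tr]], Xc)
        out[[tr]]$mean[rows] <- pr$mean
        out[[tr]]$sd[rows] <- pr$sd
        out[[tr]]$cv[rows] <- pr$cv
      }
    }
  }
  structure(list(maps = out, traits = bundle$traits, geo = geo,
                 masked = sum(!valid), scale = bundle$meta$scale),
            class = "trait_maps")
}

#' Compare two co-registered trait maps
#'
#' Paired-pixel goodness-of-fit over the common valid mask plus a
#' relative-error raster `(A - B) / B` (masked where `|B| < 1e-6`).
#'
#' @param mapA,mapB numeric matrices on the same grid (e.g. the `mean`
#'   layer of two [map_image] outputs for one trait).
#' @return A list with `stats` (rmse/nrmse/r2/n), `relative_error`
#'   (matrix), and `n_valid`.
#' @export
compare_maps <- function(mapA, mapB) {
  mapA <- as.matrix(mapA); mapB <- as.matrix(mapB)
  if (!all(dim(mapA) == dim(mapB))) {
    stop("maps are on different grids", call. = FALSE)
  }
  ok <- is.finite(mapA) & is.finite(mapB)
  if (sum(ok) < 2) stop("fewer than 2 common valid pixels", call. = FALSE)
  stats <- goodness_of_fit(mapB[ok], mapA[ok])
  rel <- matrix(NA_real_, nrow(mapA), ncol(mapA))
  denom_ok <- ok & abs(mapB) > 1e-6
  rel[denom_ok] <- (mapA[denom_ok] - mapB[denom_ok]) / mapB[denom_ok]
  list(stats = stats, relative_error = rel, n_valid = sum(ok))
}

#' Mask trait-map pixels whose uncertainty exceeds a threshold
#'
#' Generic utility: pixels with `sd > threshold` (absolute) or
#' `cv > threshold` (relative) become `NA` in all layers of that trait.
#'
#' @param maps a `trait_maps` object.
#' @param trait trait name.
#' @param threshold numeric threshold.
#' @param type `"sd"` or `"cv"`.
#' @return The modified `trait_maps`.
#' @export
mask_by_uncertainty <- function(maps, trait, threshold,
                                type = c("sd", "cv")) {
  type <- match.arg(type)
  stopifnot(inherits(maps, "trait_maps"), trait %in% maps$traits)
  bad <- maps$maps[[trait]][[type]] > threshold
  bad[is.na(bad)] <- FALSE
  for (layer in c("mean", "sd", "cv")) {
    maps$maps[[trait]][[layer]][bad] <- NA_real_
  }
  maps
}
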