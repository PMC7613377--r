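#' Read / write multiband raster imagery
#'
#' Rasters are stored as multi-page TIFF files (one 32-bit page per band,
#' values affinely rescaled to the TIFF [0, 1] payload range) together with
#' a JSON sidecar (`<path>.geo.json`) carrying the per-band scaling, the
#' geotransform (6 numbers, GDAL order), CRS string and nodata handling.
#' Missing pixels are stored in a trailing mask page. The pair round-trips
#' values to single precision and metadata exactly.
#'
#' @param path TIFF file path.
#' @return `read_raster` returns a list with `array`
#'   (rows x cols x bands) and `geo` (list with `geotransform`, `crs`,
#'   `nodata`, or `NULL`); nodata pixels are returned as `NA`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path,
                               call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".geo.json")
  meta <- if (file.exists(side)) {
    jsonlite::read_json(side, simplifyVector = TRUE)
  } else NULL
  has_mask <- isTRUE(meta$has_mask)
  nb <- length(pages) - has_mask
  arr <- array(NA_real_, c(dim(pages[[1]])[1:2], nb))
  for (b in seq_len(nb)) {
    v <- pages[[b]]
    if (length(dim(v)) == 3L) v <- v[, , 1]
    if (!is.null(meta$scale_lo)) {
      v <- meta$scale_lo[b] + v * (meta$scale_hi[b] - meta$scale_lo[b])
    }
    arr[, , b] <- v
  }
  if (has_mask) {
    mask <- pages[[nb + 1]]
    if (length(dim(mask)) == 3L) mask <- mask[, , 1]
    arr[array(rep(mask > 0.5, nb), dim(arr))] <- NA_real_
  }
  geo <- if (!is.null(meta)) {
    meta[setdiff(names(meta), c("scale_lo", "scale_hi", "has_mask"))]
  } else NULL
  if (length(geo) == 0L) geo <- NULL
  list(array = arr, geo = geo)
}

#' @rdname read_raster
#' @param arr rows x cols x bands numeric array.
#' @param geo optional list with `geotransform` (6 numbers), `crs`,
#'   `nodata`.
#' @export
write_raster <- function(arr, path, geo = NULL) {
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  nb <- dim(arr)[3]
  lo <- hi <- numeric(nb)
  has_mask <- anyNA(arr)
  pages <- vector("list", nb + has_mask)
  for (b in seq_len(nb)) {
    v <- arr[, , b]
    fin <- v[is.finite(v)]
    lo[b] <- if (length(fin)) min(fin) else 0
    hi[b] <- if (length(fin) && max(fin) > lo[b]) max(fin) else lo[b] + 1
    sc <- (v - lo[b]) / (hi[b] - lo[b])
    sc[!is.finite(sc)] <- 0
    pages[[b]] <- pmin(pmax(sc, 0), 1)
  }
  if (has_mask) {
    m <- apply(is.na(arr), c(1, 2), any)
    pages[[nb + 1]] <- m * 1
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- c(geo, list(scale_lo = lo, scale_hi = hi, has_mask = has_mask))
  jsonlite::write_json(meta, paste0(path, ".geo.json"), digits = I(17),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Write trait maps to disk
#'
#' One three-band float32 TIFF per trait (`mean`, `sd`, `cv`), nodata
#' -9999, named `<prefix>_<trait>.tif`, with geo sidecars when the source
#' raster carried geo metadata.
#'
#' @param maps a `trait_maps` object from [map_image].
#' @param prefix output path prefix.
#' @return Invisibly, the written paths.
#' @export
write_trait_maps <- function(maps, prefix) {
  stopifnot(inherits(maps, "trait_maps"))
  paths <- vapply(maps$traits, function(tr) {
    m <- maps$maps[[tr]]
    arr <- array(NA_real_, c(dim(m$mean), 3L))
    arr[, , 1] <- m$mean; arr[, , 2] <- m$sd; arr[, , 3] <- m$cv
    p <- sprintf("%s_%s.tif", prefix, tr)
    write_raster(arr, p, geo = c(maps$geo, list(nodata = -9999)))
    p
  }, character(1))
  invisible(paths)
}

#' Read a spectral response function table
#'
#' Accepts either a wide CSV (`wavelength` column plus one response column
#' per band) or a long CSV (`band, wavelength, response`). Negative
#' responses are rejected.
#'
#' @param path CSV file path.
#' @return An [srf_set].
#' @export
read_srf <- function(path) {
  tab <- utils::read.csv(path)
  if (all(c("band", "wavelength", "response") %in% names(tab))) {
    bands <- lapply(split(tab, tab$band), function(sub) {
      sub <- sub[order(sub$wavelength), ]
      list(name = as.character(sub$band[1]), wavelengths = sub$wavelength,
           response = sub$response)
    })
  } else if ("wavelength" %in% names(tab)) {
    cols <- setdiff(names(tab), "wavelength")
    if (!length(cols)) stop("SRF file has no band columns", call. = FALSE)
    bands <- lapply(cols, function(cl) {
      keep <- tab[[cl]] > 0 | c(FALSE, tab[[cl]][-nrow(tab)] > 0)
      keep <- keep | c(tab[[cl]][-1] > 0, FALSE)
      if (any(tab[[cl]] < 0)) {
        stop(sprintf("band '%s': negative response weights", cl),
             call. = FALSE)
      }
      list(name = cl, wavelengths = tab$wavelength[keep],
           response = tab[[cl]][keep])
    })
  } else {
    stop("SRF file must have a 'wavelength' column (wide) or ",
         "'band,wavelength,response' columns (long)", call. = FALSE)
  }
  srf_set(bands)
}

#' Write a goodness-of-fit report
#'
#' @param report a `gof_report` from [kfold_cv].
#' @param path CSV output path; a human-readable `.txt` twin is written
#'   alongside.
#' @return Invisibly, `path`.
#' @export
write_gof_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  txt <- sub("\\.csv$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  lines <- c("Cross-validated goodness of fit", strrep("-", 48),
             sprintf("%-8s %10s %10s %8s", "trait", "RMSE", "NRMSE(%)",
                     "R2"),
             sprintf("%-8s %10.4g %10.2f %8.3f", report$trait, report$rmse,
                     report$nrmse, report$r2))
  writeLines(lines, txt)
  invisible(path)
}

#' Run configuration with the package's reference defaults
#'
#' Reads a flat `key: value` YAML configuration (sections `noise`,
#' `vhgpr` allowed) on top of the package defaults: 1000 training samples,
#' 5 folds, additive noise 0.01, multiplicative noise 4%, the ten-band
#' default sensor configuration, 30 non-vegetated samples, geometry buffer
#' 2.5 degrees. Unknown keys are rejected (fail-fast).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A list of class `run_config`.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    n_samples = 1000L, k = 5L, n_nonveg = 30L, seed = 1L,
    scale = "BOA", provider = "surrogate", atm_provider = "parametric",
    geometry_buffer = 2.5, output_dir = ".",
    srf_file = NULL,
    noise = list(AD = 0.01, AI = 0.01, MD = 4, MI = 4),
    vhgpr = list(restarts = 3L, maxit = 500L, reltol = 1e-6,
                 jitter = 1e-8))
  if (is.null(path)) {
    cfg <- defaults
  } else {
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop("config file must be a YAML mapping",
                             call. = FALSE)
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg <- defaults
    for (nm in names(user)) {
      if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
        bad <- setdiff(names(user[[nm]]), names(defaults[[nm]]))
        if (length(bad)) {
          stop(sprintf("unknown config key(s) in '%s': %s", nm,
                       paste(bad, collapse = ", ")), call. = FALSE)
        }
        cfg[[nm]] <- utils::modifyList(defaults[[nm]], user[[nm]])
      } else {
        cfg[[nm]] <- user[[nm]]
      }
    }
  }
  if (!cfg$scale %in% c("BOA", "TOA")) {
    stop("config scale must be BOA or TOA", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Build a training database from a run configuration
#'
#' Convenience driver used by the command-line interface: builds the
#' BOA- or TOA-scale database described by a [read_config] result and
#' appends the configured non-vegetated samples.
#'
#' @param cfg a `run_config`.
#' @return A [training_db].
#' @export
build_db_from_config <- function(cfg) {
  srfs <- if (!is.null(cfg$srf_file)) read_srf(cfg$srf_file) else
    s2_default_srfs()
  db <- if (cfg$scale == "TOA") {
    build_toa_db(n = cfg$n_samples, srfs = srfs, noise = cfg$noise, seed = cfg$seed,
                 provider = cfg$provider, atm_provider = cfg$atm_provider,
                 geometry_buffer = cfg$geometry_buffer)
  } else {
    build_boa_db(n = cfg$n_samples, srfs = srfs, noise = cfg$noise, seed = cfg$seed,
                 provider = cfg$provider)
  }
  augment_nonveg(db, n_nonveg = cfg$n_nonveg, seed = cfg$seed)
}
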