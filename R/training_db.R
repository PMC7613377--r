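#' Training database of paired band reflectances and trait labels
#'
#' Created by [build_boa_db] / [build_toa_db]. A list with elements:
#' `X` (n x b band-reflectance matrix), `Y` (n x 6 trait data.frame with
#' columns `Cab`, `Cw`, `FVC`, `LAI`, `laiCab`, `laiCw`), `params` (the
#' sampled simulation variables; `NA` for appended non-vegetated rows),
#' `srfs` (the [srf_set] used), and `meta` (scale tag `"BOA"`/`"TOA"`,
#' band names and centres, seed, noise settings, provider names).
#'
#' @name training_db
NULL

trait_names <- c("Cab", "Cw", "FVC", "LAI", "laiCab", "laiCw")

make_trait_table <- function(params) {
  k <- vapply(params$ALA, extinction_coefficient, numeric(1))
  up <- upscale_traits(params$Cab, params$Cw, params$LAI)
  data.frame(Cab = params$Cab, Cw = params$Cw,
             FVC = 1 - gap_fraction(k, params$LAI), LAI = params$LAI,
             laiCab = up$laiCab, laiCw = up$laiCw)
}

new_training_db <- function(X, Y, params, srfs, meta, atm_spec = NULL,
                            atm_params = NULL) {
  stopifnot(nrow(X) == nrow(Y))
  if (any(!is.finite(X))) stop("database X contains non-finite values",
                               call. = FALSE)
  structure(list(X = X, Y = Y, params = params, srfs = srfs, meta = meta,
                 atm_spec = atm_spec, atm_params = atm_params),
            class = "training_db")
}

#' @export
print.training_db <- function(x, ...) {
  cat(sprintf("<training_db: %s scale, %d rows x %d bands, seed %s>\n",
              x$meta$scale, nrow(x$X), ncol(x$X), x$meta$seed))
  invisible(x)
}

row_state <- function(p) {
  canopy_state(N = p$N, Cab = p$Cab, Cm = p$Cm, Cw = p$Cw, LAI = p$LAI,
               ALA = p$ALA, HotS = p$HotS, skyl = p$skyl,
               alpha_soil = p$alpha_soil, theta_s = p$theta_s,
               theta_v = p$theta_v, phi = p$phi)
}

apply_db_noise <- function(X, noise, seed) {
  add_noise(X, AD = noise$AD, AI = noise$AI, MD = noise$MD, MI = noise$MI,
            seed = seed)
}

#' Build a bottom-of-atmosphere training database
#'
#' Samples canopy parameter sets, simulates top-of-canopy reflectance,
#' convolves to the sensor bands and injects the four-term noise model.
#' Trait labels (including derived FVC and the canopy-level upscalings) are
#' attached per row.
#'
#' @param n number of vegetated samples (default 1000).
#' @param spec canopy `sampling_spec` (default [default_canopy_spec]).
#' @param srfs [srf_set] (default [s2_default_srfs]).
#' @param noise list with `AD`, `AI` (reflectance units) and `MD`, `MI`
#'   (percent); default `list(AD = 0.01, AI = 0.01, MD = 4, MI = 4)`.
#' @param seed top-level integer seed; all stages derive from it.
#' @param provider TOC forward-model provider name.
#' @param grid simulation wavelength grid (nm), default 1 nm over 400-2500.
#' @param noise_stage `"band"` (default) applies the noise model to band
#'   reflectances; `"spectrum"` applies it to the full-resolution spectrum
#'   before convolution.
#' @return A [training_db] with scale tag `"BOA"`.
#' @export
build_boa_db <- function(n = 1000, spec = default_canopy_spec(),
                         srfs = s2_default_srfs(),
                         noise = list(AD = 0.01, AI = 0.01, MD = 4, MI = 4),
                         seed = 1L, provider = "surrogate",
                         grid = seq(400, 2500, by = 1),
                         noise_stage = c("band", "spectrum")) {
  noise_stage <- match.arg(noise_stage)
  params <- sample_parameters(spec, n, derive_seed(seed, "canopy"))
  specs <- lapply(seq_len(n), function(i) {
    tryCatch(simulate_toc(row_state(params[i, ]), grid, provider),
             error = function(e) stop(sprintf("row %d: %s", i,
                                              conditionMessage(e)),
                                      call. = FALSE))
  })
  if (noise_stage == "spectrum") {
    noise_seed <- derive_seed(seed, "noise")
    vals <- do.call(rbind, lapply(specs, `[[`, "values"))
    vals <- apply_db_noise(vals, noise, noise_seed)
    specs <- lapply(seq_len(n), function(i) {
      vt_spectrum(grid, pmin(pmax(vals[i, ], 0), 1), "reflectance")
    })
  }
  X <- do.call(rbind, lapply(specs, convolve_srf, srfs = srfs))
  rownames(X) <- NULL
  if (noise_stage == "band") {
    X <- apply_db_noise(X, noise, derive_seed(seed, "noise"))
  }
  meta <- list(scale = "BOA", band_names = names(srfs),
               bands = unname(srf_centers(srfs)), seed = seed, noise = noise,
               provider = provider, noise_stage = noise_stage)
  new_training_db(X, make_trait_table(params), params, srfs, meta)
}

# Random matching of canopy to atmosphere rows under a geometry buffer.
# A randomized augmenting-path bipartite matching (Kuhn's algorithm):
# adjacency lists are shuffled so the realized matching is random, while a
# perfect matching is found whenever one exists.
pair_geometries <- function(theta_s, theta_il, buffer, seed) {
  n <- length(theta_s)
  with_seed(seed, {
    adj <- lapply(seq_len(n), function(i) {
      adm <- which(abs(theta_s[i] - theta_il) <= buffer)
      if (length(adm) > 1L) sample(adm) else adm
    })
    if (any(lengths(adj) == 0L)) {
      stop(sprintf(
        "no admissible canopy-atmosphere pairing under a %g deg geometry buffer; increase the buffer",
        buffer), call. = FALSE)
    }
    env <- new.env(parent = emptyenv())
    env$match_of_atm <- integer(n)  # atmosphere row -> canopy row (0 = free)
    # process the most constrained rows first
    for (i in order(lengths(adj), sample.int(n))) {
      env$visited <- rep(FALSE, n)
      if (!augment_path(i, adj, env)) {
        stop(sprintf(
          "no admissible canopy-atmosphere pairing under a %g deg geometry buffer; increase the buffer",
          buffer), call. = FALSE)
      }
    }
    out <- integer(n)               # out[i] = atmosphere row for canopy row i
    for (j in seq_len(n)) {
      if (env$match_of_atm[j] > 0L) out[env$match_of_atm[j]] <- j
    }
    out
  })
}

# depth-first augmenting path over `env$match_of_atm` / `env$visited`
augment_path <- function(i, adj, env) {
  for (j in adj[[i]]) {
    if (!env$visited[j]) {
      env$visited[j] <- TRUE
      if (env$match_of_atm[j] == 0L ||
          augment_path(env$match_of_atm[j], adj, env)) {
        env$match_of_atm[j] <- i
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Build a top-of-atmosphere training database
#'
#' Samples canopy and atmosphere parameter sets, pairs them randomly
#' subject to a solar-zenith geometry buffer, resamples the top-of-canopy
#' spectra to the atmosphere grid, couples them to top-of-atmosphere
#' reflectance, convolves to the sensor bands and injects noise. Canopy
#' draws use the same derived seed as [build_boa_db], so BOA and TOA
#' databases built from one top-level seed share identical trait labels.
#'
#' @inheritParams build_boa_db
#' @param atm_spec atmosphere `sampling_spec`
#'   (default [default_atmosphere_spec]).
#' @param atm_provider `"parametric"` or `"lut-adapter"`.
#' @param lut optional LUT object for the adapter provider.
#' @param geometry_buffer maximum allowed difference (degrees) between the
#'   canopy sun zenith and the atmosphere solar zenith in a pair
#'   (default 2.5).
#' @param toc_grid canopy simulation grid (nm, default 1 nm).
#' @param atm_grid atmosphere/coupling grid (nm, default 2.5 nm).
#' @return A [training_db] with scale tag `"TOA"` (band reflectances are
#'   TOA reflectance).
#' @export
build_toa_db <- function(n = 1000, spec = default_canopy_spec(),
                         atm_spec = default_atmosphere_spec(),
                         srfs = s2_default_srfs(),
                         noise = list(AD = 0.01, AI = 0.01, MD = 4, MI = 4),
                         seed = 1L, provider = "surrogate",
                         atm_provider = "parametric", lut = NULL,
                         geometry_buffer = 2.5,
                         toc_grid = seq(400, 2500, by = 1),
                         atm_grid = seq(400, 2500, by = 2.5)) {
  params <- sample_parameters(spec, n, derive_seed(seed, "canopy"))
  atm_params <- sample_parameters(atm_spec, n, derive_seed(seed, "atmosphere"))
  pairing <- pair_geometries(params$theta_s, atm_params$theta_il,
                             geometry_buffer, derive_seed(seed, "pairing"))
  atm_params <- atm_params[pairing, , drop = FALSE]
  rownames(atm_params) <- NULL
  X <- matrix(NA_real_, n, length(srfs))
  for (i in seq_len(n)) {
    toc <- simulate_toc(row_state(params[i, ]), toc_grid, provider)
    toc <- resample_spectrum(toc, atm_grid)
    ast <- atmosphere_state(O3C = atm_params$O3C[i], CWV = atm_params$CWV[i],
                            AOT = atm_params$AOT[i],
                            ALPHA = atm_params$ALPHA[i], G = atm_params$G[i],
                            theta_il = atm_params$theta_il[i])
    tf <- simulate_transfer_functions(ast, atm_grid, atm_provider, lut = lut)
    toa <- couple_to_toa(toc, tf, ast$theta_il)
    X[i, ] <- convolve_srf(toa$rho_toa, srfs)
  }
  colnames(X) <- names(srfs)
  X <- apply_db_noise(X, noise, derive_seed(seed, "noise"))
  meta <- list(scale = "TOA", band_names = names(srfs),
               bands = unname(srf_centers(srfs)), seed = seed, noise = noise,
               provider = provider, atm_provider = atm_provider,
               geometry_buffer = geometry_buffer, noise_stage = "band")
  new_training_db(X, make_trait_table(params), params, srfs, meta,
                  atm_spec = atm_spec, atm_params = atm_params)
}

# synthetic non-vegetated top-of-canopy spectra (labelled zero for all traits)
nonveg_spectrum <- function(type, grid) {
  basis <- load_basis("surrogate")
  vals <- switch(
    type,
    soil_bright = stats::runif(1, 0.55, 0.95) * pmax(basis$funs$soil(grid), 0),
    soil_dark = stats::runif(1, 0.05, 0.35) * pmax(basis$funs$soil(grid), 0),
    manmade = rep(stats::runif(1, 0.05, 0.5), length(grid)),
    water = 0.005 + stats::runif(1, 0.04, 0.08) * exp(-(grid - 400) / 150),
    stop("unknown non-vegetated type: ", type)
  )
  vt_spectrum(grid, pmin(pmax(vals, 0), 1), "reflectance")
}

#' Append synthetic non-vegetated samples to a training database
#'
#' Adds bright/dark soil, flat grey man-made and water-like low-NIR spectra
#' with all-zero trait labels, mirroring the practice of augmenting a
#' vegetation-only simulated database with non-vegetated surfaces so the
#' regressors learn to map them to zero traits. For a TOA-scale database
#' each synthetic surface is coupled through a freshly sampled atmosphere
#' state before convolution.
#'
#' @param db a [training_db].
#' @param n_nonveg number of samples to append (default 30).
#' @param seed integer seed.
#' @return The augmented [training_db]; row count grows by `n_nonveg`.
#' @export
augment_nonveg <- function(db, n_nonveg = 30, seed = 1L) {
  stopifnot(inherits(db, "training_db"))
  if (n_nonveg == 0) return(db)
  if (is.null(db$srfs)) {
    stop("database carries no SRF set; cannot synthesize band values",
         call. = FALSE)
  }
  types <- rep(c("soil_bright", "soil_dark", "manmade", "water"),
               length.out = n_nonveg)
  grid <- seq(400, 2500, by = if (db$meta$scale == "TOA") 2.5 else 1)
  sd_seed <- derive_seed(seed, "nonveg")
  Xn <- with_seed(sd_seed, {
    if (db$meta$scale == "TOA") {
      atm_spec <- if (!is.null(db$atm_spec)) db$atm_spec else
        default_atmosphere_spec()
      ap <- sample_parameters(atm_spec, n_nonveg,
                              derive_seed(sd_seed, "atmosphere"))
      do.call(rbind, lapply(seq_len(n_nonveg), function(i) {
        sp <- nonveg_spectrum(types[i], grid)
        ast <- atmosphere_state(O3C = ap$O3C[i], CWV = ap$CWV[i],
                                AOT = ap$AOT[i], ALPHA = ap$ALPHA[i],
                                G = ap$G[i], theta_il = ap$theta_il[i])
        tf <- simulate_transfer_functions(ast, grid, "parametric")
        convolve_srf(couple_to_toa(sp, tf, ast$theta_il)$rho_toa, db$srfs)
      }))
    } else {
      do.call(rbind, lapply(seq_len(n_nonveg), function(i) {
        convolve_srf(nonveg_spectrum(types[i], grid), db$srfs)
      }))
    }
  })
  Xn <- apply_db_noise(Xn, db$meta$noise, derive_seed(sd_seed, "noise"))
  colnames(Xn) <- colnames(db$X)
  Yn <- as.data.frame(matrix(0, n_nonveg, length(trait_names)))
  names(Yn) <- trait_names
  pn <- db$params[rep(NA_integer_, n_nonveg), , drop = FALSE]
  rownames(pn) <- NULL
  db$X <- rbind(db$X, Xn)
  db$Y <- rbind(db$Y, Yn)
  db$params <- rbind(db$params, pn)
  db$meta$n_nonveg <- (db$meta$n_nonveg %||% 0) + n_nonveg
  db$meta$nonveg_types <- types
  db
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a training database as delimited text
#'
#' CSV with a `# key=value` comment-header block carrying the metadata
#' (scale, seed, noise settings, provider, band names/centres), then one
#' row per sample with `band_*`, `trait_*` and `param_*` columns.
#'
#' @param db a [training_db].
#' @param path file path.
#' @return `db_write` returns `path` invisibly; `db_read` a [training_db]
#'   (without the SRF curves, which are not serialized; band centres are).
#' @export
db_write <- function(db, path) {
  stopifnot(inherits(db, "training_db"))
  meta <- db$meta
  hdr <- c(
    sprintf("# scale=%s", meta$scale),
    sprintf("# seed=%s", meta$seed),
    sprintf("# provider=%s", meta$provider),
    sprintf("# noise=AD:%g,AI:%g,MD:%g,MI:%g", meta$noise$AD, meta$noise$AI,
            meta$noise$MD, meta$noise$MI),
    sprintf("# band_names=%s", paste(meta$band_names, collapse = ";")),
    sprintf("# bands=%s", paste(format(meta$bands, digits = 10),
                                collapse = ";")),
    sprintf("# n_nonveg=%d", meta$n_nonveg %||% 0L)
  )
  Xd <- as.data.frame(db$X)
  names(Xd) <- paste0("band_", meta$band_names)
  Yd <- db$Y
  names(Yd) <- paste0("trait_", names(db$Y))
  Pd <- db$params
  names(Pd) <- paste0("param_", names(db$params))
  tab <- cbind(Xd, Yd, Pd)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(format(tab, digits = 12, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname db_write
#' @export
db_read <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^# *", "", hdr), "=", fixed = TRUE)
  meta_raw <- stats::setNames(vapply(kv, function(x)
    paste(x[-1], collapse = "="), character(1)),
    vapply(kv, `[[`, character(1), 1))
  tab <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  noise_parts <- strsplit(strsplit(meta_raw[["noise"]], ",")[[1]], ":")
  noise <- stats::setNames(
    lapply(noise_parts, function(x) as.numeric(x[2])),
    vapply(noise_parts, `[[`, character(1), 1))
  meta <- list(scale = meta_raw[["scale"]],
               seed = as.integer(meta_raw[["seed"]]),
               provider = meta_raw[["provider"]], noise = noise,
               band_names = strsplit(meta_raw[["band_names"]], ";")[[1]],
               bands = as.numeric(strsplit(meta_raw[["bands"]], ";")[[1]]),
               n_nonveg = as.integer(meta_raw[["n_nonveg"]]))
  X <- as.matrix(tab[grep("^band_", names(tab))])
  colnames(X) <- sub("^band_", "", colnames(X))
  Y <- tab[grep("^trait_", names(tab))]
  names(Y) <- sub("^trait_", "", names(Y))
  params <- tab[grep("^param_", names(tab))]
  names(params) <- sub("^param_", "", names(params))
  new_training_db(X, Y, params, srfs = NULL, meta = meta)
}
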