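#' Spectral response function set
#'
#' A set of per-band response curves used to convolve high-resolution
#' spectra to sensor bands. Each band is a list
#' `list(name, wavelengths, response)` with nonnegative response weights.
#'
#' @param bands list of band entries.
#' @return An object of class `srf_set`.
#' @export
srf_set <- function(bands) {
  stopifnot(is.list(bands), length(bands) >= 1L)
  for (b in bands) {
    if (is.null(b$name) || is.null(b$wavelengths) || is.null(b$response)) {
      stop("each SRF band needs name, wavelengths and response",
           call. = FALSE)
    }
    if (length(b$wavelengths) != length(b$response)) {
      stop(sprintf("band '%s': wavelengths/response length mismatch",
                   b$name), call. = FALSE)
    }
    if (any(b$response < 0)) {
      stop(sprintf("band '%s': negative response weights", b$name),
           call. = FALSE)
    }
    if (sum(b$response) <= 0) {
      stop(sprintf("band '%s': response must integrate to a positive value",
                   b$name), call. = FALSE)
    }
    if (any(diff(b$wavelengths) <= 0)) {
      stop(sprintf("band '%s': wavelengths must be strictly increasing",
                   b$name), call. = FALSE)
    }
  }
  names(bands) <- vapply(bands, `[[`, character(1), "name")
  structure(bands, class = "srf_set")
}

#' Band centres of an SRF set (response-weighted)
#' @param srfs an [srf_set].
#' @return Named numeric vector of centre wavelengths (nm).
#' @export
srf_centers <- function(srfs) {
  vapply(srfs, function(b) sum(b$wavelengths * b$response) / sum(b$response),
         numeric(1))
}

#' Default ten-band multispectral configuration
#'
#' Gaussian response curves at the ten 10-20 m Sentinel-2 band centres used
#' throughout the package (493, 560, 665, 704, 740, 783, 833, 865, 1610,
#' 2190 nm), with full-widths at half maximum matching the nominal S2A
#' bandwidths. The three 60 m atmospheric bands are excluded by design.
#' Measured response tables can be supplied instead via [read_srf] and take
#' precedence wherever an `srf_set` is accepted.
#'
#' @return An [srf_set] with ten bands.
#' @export
s2_default_srfs <- function() {
  centers <- c(B2 = 493, B3 = 560, B4 = 665, B5 = 704, B6 = 740,
               B7 = 783, B8 = 833, B8A = 865, B11 = 1610, B12 = 2190)
  fwhm <- c(B2 = 66, B3 = 36, B4 = 31, B5 = 15, B6 = 15,
            B7 = 20, B8 = 106, B8A = 21, B11 = 91, B12 = 175)
  bands <- lapply(names(centers), function(nm) {
    c0 <- centers[[nm]]
    sigma <- fwhm[[nm]] / (2 * sqrt(2 * log(2)))
    wl <- seq(round(c0 - 3 * sigma), round(c0 + 3 * sigma), by = 1)
    list(name = nm, wavelengths = wl,
         response = exp(-0.5 * ((wl - c0) / sigma)^2))
  })
  srf_set(bands)
}

#' Convolve a spectrum to sensor bands
#'
#' Per band, the response-weighted mean of the spectrum over the band's
#' wavelength samples: `sum(R * w) / sum(w)` evaluated on the SRF's own
#' grid (the spectrum is spline-interpolated onto it). For a uniform SRF
#' grid this is the discrete response-weighted average, so a boxcar
#' response returns the plain mean of the covered samples and a symmetric
#' response applied to a linear spectrum returns the value at the band
#' centre.
#'
#' @param spec a reflectance or radiance [vt_spectrum].
#' @param srfs an [srf_set] whose support lies within the spectrum grid.
#' @return Named numeric vector, one value per band.
#' @export
convolve_srf <- function(spec, srfs) {
  stopifnot(inherits(spec, "vt_spectrum"), inherits(srfs, "srf_set"))
  vapply(srfs, function(b) {
    if (min(b$wavelengths) < min(spec$wavelengths) ||
        max(b$wavelengths) > max(spec$wavelengths)) {
      stop(sprintf(
        "band '%s' support [%g, %g] nm not covered by the spectrum grid",
        b$name, min(b$wavelengths), max(b$wavelengths)), call. = FALSE)
    }
    r <- stats::splinefun(spec$wavelengths, spec$values,
                          method = "fmm")(b$wavelengths)
    sum(r * b$response) / sum(b$response)
  }, numeric(1))
}

#' Apply the four-term reflectance noise model
#'
#' `R*(l) = R(l) * (1 + (MD(l) + MI) / 100) + AD(l) + AI` with
#' wavelength-dependent terms (`MD`, `AD`) drawn independently per band and
#' per spectrum and wavelength-independent terms (`MI`, `AI`) drawn once per
#' spectrum; all draws are zero-mean Gaussian with the stated magnitudes as
#' standard deviations, so the noise is unbiased. In `deterministic` mode
#' the draws are replaced by the magnitudes themselves (useful for worked
#' examples).
#'
#' @param X n x b matrix of band reflectances (rows = spectra).
#' @param AD,AI additive wavelength-dependent / -independent noise
#'   magnitudes (reflectance units; defaults 0.01).
#' @param MD,MI multiplicative wavelength-dependent / -independent noise
#'   magnitudes in percent (defaults 4).
#' @param seed integer seed.
#' @param deterministic replace Gaussian draws by their standard deviations.
#' @return Matrix of the same shape as `X`.
#' @export
add_noise <- function(X, AD = 0.01, AI = 0.01, MD = 4, MI = 4,
                      seed = 1L, deterministic = FALSE) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X must be finite", call. = FALSE)
  if (AD < 0 || AI < 0 || MD < 0 || MI < 0) {
    stop("noise magnitudes must be nonnegative", call. = FALSE)
  }
  n <- nrow(X); b <- ncol(X)
  if (deterministic) {
    return(X * (1 + (MD + MI) / 100) + AD + AI)
  }
  if (AD == 0 && AI == 0 && MD == 0 && MI == 0) return(X)
  with_seed(seed, {
    md <- matrix(stats::rnorm(n * b, 0, MD), n, b)
    ad <- matrix(stats::rnorm(n * b, 0, AD), n, b)
    mi <- stats::rnorm(n, 0, MI)
    ai <- stats::rnorm(n, 0, AI)
    X * (1 + (md + mi) / 100) + ad + ai
  })
}
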