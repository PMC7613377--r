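#' Canopy state: one draw of leaf, canopy and geometry variables
#'
#' Bundles the leaf (structure `N`, chlorophyll `Cab`, dry matter `Cm`,
#' water `Cw`), canopy (`LAI`, average leaf angle `ALA`, hot spot `HotS`,
#' diffuse fraction `skyl`, soil brightness `alpha_soil`) and geometry
#' (`theta_s`, `theta_v`, `phi`) variables that drive a top-of-canopy
#' reflectance simulation.
#'
#' @param N leaf structure parameter (unitless, >= 1).
#' @param Cab leaf chlorophyll a+b content (ug/cm2, >= 0).
#' @param Cm leaf dry matter content (g/cm2, >= 0).
#' @param Cw leaf water content, equivalent water thickness (cm, >= 0).
#' @param LAI leaf area index (m2/m2, >= 0).
#' @param ALA average leaf inclination angle (degrees, in (0, 90)).
#' @param HotS hot spot parameter (m/m).
#' @param skyl diffuse incoming solar fraction.
#' @param alpha_soil soil brightness scaling factor in `[0, 1]`.
#' @param theta_s sun zenith angle (degrees, in `[0, 90)`).
#' @param theta_v view zenith angle (degrees).
#' @param phi sun-sensor relative azimuth (degrees).
#' @return An object of class `canopy_state` (named list).
#' @examples
#' st <- canopy_state(Cab = 45, LAI = 3)
#' compute_fvc(st)
#' @export
canopy_state <- function(N = 1.9, Cab = 40, Cm = 0.005, Cw = 0.02,
                         LAI = 3, ALA = 55, HotS = 0.01, skyl = 0.05,
                         alpha_soil = 0.5, theta_s = 25, theta_v = 0,
                         phi = 0) {
  st <- list(N = N, Cab = Cab, Cm = Cm, Cw = Cw, LAI = LAI, ALA = ALA,
             HotS = HotS, skyl = skyl, alpha_soil = alpha_soil,
             theta_s = theta_s, theta_v = theta_v, phi = phi)
  for (nm in names(st)) {
    v <- st[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("canopy state variable '%s' must be a finite scalar", nm),
           call. = FALSE)
    }
  }
  if (st$LAI < 0) stop("LAI must be >= 0", call. = FALSE)
  if (st$Cab < 0 || st$Cw < 0 || st$Cm < 0) {
    stop("leaf contents (Cab, Cw, Cm) must be >= 0", call. = FALSE)
  }
  if (st$alpha_soil < 0 || st$alpha_soil > 1) {
    stop("alpha_soil must lie in [0, 1]", call. = FALSE)
  }
  if (st$ALA <= 0 || st$ALA >= 90) stop("ALA must lie in (0, 90) degrees",
                                        call. = FALSE)
  if (st$theta_s < 0 || st$theta_s >= 90) {
    stop("theta_s must lie in [0, 90) degrees", call. = FALSE)
  }
  structure(st, class = "canopy_state")
}

#' Canopy gap fraction from Beer's law
#'
#' `P = exp(-k * LAI)`: the probability that a view ray passes through the
#' canopy without hitting foliage, for extinction coefficient `k` and leaf
#' area index `LAI`.
#'
#' @param k extinction coefficient (>= 0).
#' @param LAI leaf area index (>= 0). Vectorised over both arguments.
#' @return Gap fraction in `(0, 1]`.
#' @export
gap_fraction <- function(k, LAI) {
  if (any(k < 0) || any(LAI < 0)) {
    stop("gap_fraction requires k >= 0 and LAI >= 0", call. = FALSE)
  }
  exp(-k * LAI)
}

# Ellipsoidal leaf-angle distribution machinery (Campbell-style).
# x is the ratio of horizontal to vertical semi-axes of the leaf-normal
# ellipsoid; x = 1 is the spherical distribution (mean angle ~57.3 deg).

# mean leaf inclination (degrees) of the ellipsoidal distribution
ellipsoidal_mean_angle <- function(x) {
  dens <- function(th) 2 * x^3 * sin(th) / (cos(th)^2 + x^2 * sin(th)^2)^2
  z <- stats::integrate(dens, 0, pi / 2, rel.tol = 1e-10)$value
  m <- stats::integrate(function(th) th * dens(th), 0, pi / 2,
                        rel.tol = 1e-10)$value
  (m / z) * 180 / pi
}

# invert ALA (deg) -> ellipsoid parameter x, cached on a fine grid
ala_to_x <- function(ALA) {
  cache <- get_cache()
  if (is.null(cache$ala_spline)) {
    xs <- exp(seq(log(0.05), log(20), length.out = 160))
    alas <- vapply(xs, ellipsoidal_mean_angle, numeric(1))
    # mean angle decreases monotonically with x
    cache$ala_spline <- stats::splinefun(rev(alas), rev(log(xs)),
                                         method = "hyman")
    cache$ala_range <- range(alas)
  }
  if (ALA < cache$ala_range[1] || ALA > cache$ala_range[2]) {
    stop(sprintf("ALA = %g deg outside the invertible range [%.1f, %.1f]",
                 ALA, cache$ala_range[1], cache$ala_range[2]), call. = FALSE)
  }
  exp(cache$ala_spline(ALA))
}

#' Nadir extinction coefficient of an ellipsoidal leaf-angle distribution
#'
#' The canopy extinction coefficient at nadir view for an ellipsoidal
#' leaf-angle distribution whose parameter is chosen so that its mean leaf
#' inclination equals `ALA`. For the spherical distribution
#' (`ALA` ~ 57.3 degrees) this evaluates to ~0.5.
#'
#' @param ALA average leaf inclination angle in degrees.
#' @param theta_v view zenith angle in degrees (default nadir).
#' @return Extinction coefficient (unitless).
#' @export
extinction_coefficient <- function(ALA, theta_v = 0) {
  x <- ala_to_x(ALA)
  tv <- theta_v * pi / 180
  sqrt(x^2 + tan(tv)^2) / (x + 1.774 * (x + 1.182)^(-0.733))
}

#' Fractional vegetation cover from the nadir gap fraction
#'
#' `FVC = 1 - exp(-k * LAI)` with `k` the nadir extinction coefficient of
#' the ellipsoidal leaf-angle distribution matching the state's average
#' leaf angle.
#'
#' @param state a [canopy_state], or a numeric LAI when `ALA` is given.
#' @param ALA average leaf angle (degrees); only used when `state` is numeric.
#' @return FVC in `[0, 1)`.
#' @export
compute_fvc <- function(state, ALA = NULL) {
  if (inherits(state, "canopy_state")) {
    LAI <- state$LAI
    ALA <- state$ALA
  } else {
    LAI <- state
    if (is.null(ALA)) stop("ALA required when state is a bare LAI",
                           call. = FALSE)
  }
  k <- extinction_coefficient(ALA)
  1 - gap_fraction(k, LAI)
}

#' Upscale leaf traits to the canopy level
#'
#' Canopy chlorophyll content `laiCab = LAI * Cab * 0.01` (ug/cm2 to g/m2)
#' and canopy water content `laiCw = LAI * Cw * 1e4` (cm of water to g/m2,
#' water density 1 g/cm3).
#'
#' @param Cab leaf chlorophyll content (ug/cm2).
#' @param Cw leaf water content (cm).
#' @param LAI leaf area index (m2/m2). All vectorised.
#' @return A list with `laiCab` and `laiCw` in g/m2.
#' @examples
#' upscale_traits(Cab = 44.68, Cw = 0.020, LAI = 3.60)
#' @export
upscale_traits <- function(Cab, Cw, LAI) {
  if (any(Cab < 0) || any(Cw < 0) || any(LAI < 0)) {
    stop("upscale_traits requires nonnegative inputs", call. = FALSE)
  }
  list(laiCab = LAI * Cab * 0.01, laiCw = LAI * Cw * 1e4)
}

## ---- forward-model provider registry ---------------------------------------

get_cache <- function() {
  if (!exists("cache_env", envir = .vt_env, inherits = FALSE)) {
    assign("cache_env", new.env(parent = emptyenv()), envir = .vt_env)
  }
  get("cache_env", envir = .vt_env)
}

.vt_env <- new.env(parent = emptyenv())

#' Register a top-of-canopy forward-model provider
#'
#' Providers map a [canopy_state] and wavelength grid to a reflectance
#' [vt_spectrum]. The bundled `"surrogate"` provider is registered
#' automatically; an external radiative-transfer code (e.g. a PROSPECT+SAIL
#' implementation) can be plugged in under the name `"prosail-adapter"`.
#'
#' @param name provider name.
#' @param fn function of `(state, grid)` returning a reflectance
#'   [vt_spectrum] on `grid`.
#' @return Invisibly, the provider name.
#' @export
register_toc_provider <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = toc_registry())
  invisible(name)
}

toc_registry <- function() {
  if (!exists("toc_providers", envir = .vt_env, inherits = FALSE)) {
    assign("toc_providers", new.env(parent = emptyenv()), envir = .vt_env)
  }
  get("toc_providers", envir = .vt_env)
}

#' Simulate top-of-canopy bidirectional reflectance
#'
#' Dispatches a canopy state to a registered forward-model provider and
#' returns the reflectance spectrum on the requested grid. Deterministic for
#' a fixed state and provider.
#'
#' @param state a [canopy_state].
#' @param grid wavelength grid (nm), strictly increasing.
#' @param provider provider name; `"surrogate"` (bundled) or
#'   `"prosail-adapter"` (requires [register_toc_provider]).
#' @return A reflectance [vt_spectrum].
#' @export
simulate_toc <- function(state, grid = seq(400, 2500, by = 1),
                         provider = "surrogate") {
  stopifnot(inherits(state, "canopy_state"))
  reg <- toc_registry()
  if (!exists(provider, envir = reg, inherits = FALSE)) {
    if (identical(provider, "prosail-adapter")) {
      stop("no external PROSPECT+SAIL backend registered; call ",
           "register_toc_provider(\"prosail-adapter\", fn) first",
           call. = FALSE)
    }
    stop(sprintf("unknown TOC provider '%s'; registered: %s", provider,
                 paste(ls(reg), collapse = ", ")), call. = FALSE)
  }
  fn <- get(provider, envir = reg)
  out <- fn(state, as.numeric(grid))
  if (!inherits(out, "vt_spectrum") || out$quantity != "reflectance") {
    stop("provider must return a reflectance vt_spectrum", call. = FALSE)
  }
  out
}

## ---- bundled surrogate canopy model -----------------------------------------

# Load and spline the frozen basis tables shipped in inst/extdata.
load_basis <- function(which = c("surrogate", "atmosphere")) {
  which <- match.arg(which)
  cache <- get_cache()
  key <- paste0("basis_", which)
  if (is.null(cache[[key]])) {
    path <- system.file("extdata", paste0(which, "_basis.csv"),
                        package = "vhtraits")
    if (!nzchar(path)) stop("bundled basis table missing: ", which)
    tab <- utils::read.csv(path)
    funs <- lapply(setdiff(names(tab), "wavelength"), function(col) {
      stats::splinefun(tab$wavelength, tab[[col]], method = "fmm")
    })
    names(funs) <- setdiff(names(tab), "wavelength")
    cache[[key]] <- list(table = tab, funs = funs,
                         support = range(tab$wavelength))
  }
  cache[[key]]
}

#' Bare-soil reflectance of the bundled surrogate model
#'
#' The soil spectrum the surrogate canopy model mixes under the canopy:
#' a smooth dry-soil curve scaled linearly by `alpha_soil`.
#'
#' @param grid wavelength grid (nm).
#' @param alpha_soil brightness scaling in `[0, 1]`.
#' @return A reflectance [vt_spectrum].
#' @export
surrogate_soil <- function(grid, alpha_soil = 0.5) {
  basis <- load_basis("surrogate")
  vt_spectrum(grid, pmax(alpha_soil * basis$funs$soil(grid), 0),
              "reflectance")
}

# Surrogate TOC model. NOT a physical radiative-transfer model: a frozen
# linear mixture of soil and an absorbing leaf layer, designed so every
# trait has a qualitatively monotone, sign-correct spectral effect:
#   rho = (1 - FVC_eff) * alpha_soil * soil(lambda)
#       + FVC_eff * leaf(lambda) * scatter(N)
#         * exp(-(a_cab*Cab + a_w*Cw + a_m*Cm) * D(LAI)) * geom(theta_s)
# with FVC_eff = 1 - exp(-k(ALA) * LAI) the nadir gap-fraction cover and
# D(LAI) = 1 + 2*(1 - exp(-LAI/2)) a saturating Beer-Lambert depth factor.
surrogate_toc <- function(state, grid) {
  basis <- load_basis("surrogate")
  if (min(grid) < basis$support[1] || max(grid) > basis$support[2]) {
    stop(sprintf("surrogate provider supports %g-%g nm",
                 basis$support[1], basis$support[2]), call. = FALSE)
  }
  for (nm in c("Cab", "Cw", "Cm")) {
    lim <- c(Cab = 120, Cw = 0.2, Cm = 0.1)[[nm]]
    if (state[[nm]] > lim) {
      stop(sprintf("surrogate domain error: %s = %g exceeds %g", nm,
                   state[[nm]], lim), call. = FALSE)
    }
  }
  k <- extinction_coefficient(state$ALA)
  fvc_eff <- 1 - gap_fraction(k, state$LAI)
  depth <- 1 + 2 * (1 - exp(-state$LAI / 2))
  absorb <- exp(-(basis$funs$a_cab(grid) * state$Cab +
                    basis$funs$a_w(grid) * state$Cw +
                    basis$funs$a_m(grid) * state$Cm) * depth)
  scatter <- 0.9 + 0.12 * (state$N - 1.3)
  geom <- (cos(state$theta_s * pi / 180) / cos(25 * pi / 180))^0.25
  leaf <- pmax(basis$funs$leaf(grid), 0) * scatter * absorb * geom
  soil <- pmax(state$alpha_soil * basis$funs$soil(grid), 0)
  rho <- (1 - fvc_eff) * soil + fvc_eff * leaf
  vt_spectrum(grid, pmin(pmax(rho, 0), 1), "reflectance")
}

register_builtin_providers <- function() {
  register_toc_provider("surrogate", surrogate_toc)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_providers()
}
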