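#' Atmosphere state: one draw of the atmospheric variables
#'
#' @param O3C ozone column (atm-cm).
#' @param CWV columnar water vapour (g/cm2).
#' @param AOT aerosol optical thickness at 550 nm.
#' @param ALPHA Angstrom coefficient of the aerosol spectral law.
#' @param G Henyey-Greenstein asymmetry factor in `(0, 1)`.
#' @param theta_il solar zenith angle (degrees).
#' @return An object of class `atmosphere_state`.
#' @export
atmosphere_state <- function(O3C = 0.3, CWV = 2, AOT = 0.2, ALPHA = 1.2,
                             G = 0.8, theta_il = 25) {
  st <- list(O3C = O3C, CWV = CWV, AOT = AOT, ALPHA = ALPHA, G = G,
             theta_il = theta_il)
  for (nm in names(st)) {
    v <- st[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("atmosphere variable '%s' must be a finite scalar", nm),
           call. = FALSE)
    }
  }
  if (st$O3C < 0 || st$CWV < 0 || st$AOT < 0) {
    stop("O3C, CWV and AOT must be >= 0", call. = FALSE)
  }
  if (st$G < 0 || st$G >= 1) stop("G must lie in [0, 1)", call. = FALSE)
  if (st$theta_il < 0 || st$theta_il >= 90) {
    stop("theta_il must lie in [0, 90) degrees", call. = FALSE)
  }
  structure(st, class = "atmosphere_state")
}

#' Construct a set of atmospheric transfer functions
#'
#' Collects the six spectral functions needed by the top-of-atmosphere
#' coupling on a common wavelength grid: intrinsic atmospheric reflectance
#' `rho0`, total gas transmittance `Tgas`, downward/upward scattering
#' transmittances `Tdwn`/`Tup`, spherical albedo `S`, and extraterrestrial
#' solar irradiance `I0` (mW m-2 nm-1).
#'
#' @param wavelengths common wavelength grid (nm).
#' @param rho0,tgas,tdwn,tup,s,i0 numeric vectors on that grid.
#' @return An object of class `transfer_functions`.
#' @export
transfer_functions <- function(wavelengths, rho0, tgas, tdwn, tup, s, i0) {
  wavelengths <- as.numeric(wavelengths)
  n <- length(wavelengths)
  parts <- list(rho0 = rho0, tgas = tgas, tdwn = tdwn, tup = tup,
                s = s, i0 = i0)
  for (nm in names(parts)) {
    if (length(parts[[nm]]) != n || any(!is.finite(parts[[nm]]))) {
      stop(sprintf("transfer function '%s' must be finite and match the grid",
                   nm), call. = FALSE)
    }
  }
  tol <- 1e-9
  for (nm in c("tgas", "tdwn", "tup")) {
    if (any(parts[[nm]] < -tol) || any(parts[[nm]] > 1 + tol)) {
      stop(sprintf("transmittance '%s' must lie in [0, 1]", nm),
           call. = FALSE)
    }
  }
  if (any(parts$s < -tol) || any(parts$s >= 1)) {
    stop("spherical albedo must lie in [0, 1)", call. = FALSE)
  }
  if (any(parts$rho0 < -tol)) stop("rho0 must be >= 0", call. = FALSE)
  if (any(parts$i0 <= 0)) stop("I0 must be > 0", call. = FALSE)
  structure(c(list(wavelengths = wavelengths), parts),
            class = "transfer_functions")
}

#' Bundled extraterrestrial solar irradiance curve
#'
#' Smooth reference solar spectral irradiance (mW m-2 nm-1) used as the
#' default `I0` of the parametric atmosphere.
#'
#' @param grid wavelength grid (nm).
#' @return Numeric vector of irradiances.
#' @export
solar_irradiance <- function(grid) {
  basis <- load_basis("atmosphere")
  pmax(basis$funs$e0(grid), 1e-6)
}

# Rayleigh optical depth (Hansen & Travis style analytic fit), lambda in nm
rayleigh_od <- function(grid) {
  um <- grid / 1000
  0.008569 * um^-4 * (1 + 0.0113 * um^-2 + 0.00013 * um^-4)
}

#' Simulate atmospheric transfer functions
#'
#' The bundled `"parametric"` provider is a compact analytic atmosphere:
#' Rayleigh scattering from a standard analytic optical-depth fit, an
#' Angstrom-law aerosol with Henyey-Greenstein phase function, and smooth
#' bundled absorption shapes for ozone and water vapour. It is designed so
#' every atmospheric variable has a monotone, sign-correct spectral effect;
#' it makes no claim to reproduce any particular reference atmosphere code.
#' Tables exported from an external atmospheric RTM can be used instead via
#' the `"lut-adapter"` provider (see [read_atmosphere_lut]).
#'
#' @param state an [atmosphere_state].
#' @param grid wavelength grid (nm).
#' @param provider `"parametric"` or `"lut-adapter"`.
#' @param lut for `provider = "lut-adapter"`, an object from
#'   [read_atmosphere_lut].
#' @return A [transfer_functions] object.
#' @export
simulate_transfer_functions <- function(state, grid = seq(400, 2500, by = 2.5),
                                        provider = c("parametric",
                                                     "lut-adapter"),
                                        lut = NULL) {
  stopifnot(inherits(state, "atmosphere_state"))
  provider <- match.arg(provider)
  grid <- as.numeric(grid)
  if (provider == "lut-adapter") {
    if (is.null(lut)) stop("lut-adapter provider needs a lut object",
                           call. = FALSE)
    return(interpolate_atmosphere_lut(lut, state, grid))
  }

  basis <- load_basis("atmosphere")
  mu_s <- cos(state$theta_il * pi / 180)
  mu_v <- 1  # nadir view path

  tau_r <- rayleigh_od(grid)
  tau_a <- state$AOT * (grid / 550)^(-state$ALPHA)
  omega_a <- 0.95                      # fixed aerosol single-scattering albedo
  f_fwd <- (1 + state$G) / 2           # HG forward-hemisphere fraction
  # effective extinction: half the Rayleigh scattering plus the absorbed and
  # backward-scattered aerosol fractions
  tau_eff <- 0.5 * tau_r + (1 - omega_a) * tau_a +
    omega_a * (1 - f_fwd) * tau_a
  tdwn <- exp(-tau_eff / mu_s)
  tup <- exp(-tau_eff / mu_v)

  b_h2o <- 0.6                          # curve-of-growth exponent
  tgas <- exp(-basis$funs$a_o3(grid) * state$O3C -
                basis$funs$a_h2o(grid) * state$CWV^b_h2o)

  # single-scattering path reflectance at the backscatter geometry
  cos_theta_sc <- -mu_s * mu_v
  p_ray <- 0.75 * (1 + cos_theta_sc^2)
  p_hg <- (1 - state$G^2) /
    (1 + state$G^2 - 2 * state$G * cos_theta_sc)^1.5
  rho0 <- (tau_r * p_ray + omega_a * tau_a * p_hg) / (4 * mu_s * mu_v)

  sr <- 0.92 * tau_r
  sa <- 0.33 * (1 - state$G) * omega_a * tau_a
  s <- sr / (1 + sr) + sa / (1 + sa)
  s <- pmin(s, 0.999)

  transfer_functions(grid, rho0 = pmax(rho0, 0), tgas = pmin(pmax(tgas, 0), 1),
                     tdwn = pmin(pmax(tdwn, 0), 1),
                     tup = pmin(pmax(tup, 0), 1), s = pmax(s, 0),
                     i0 = solar_irradiance(grid))
}

#' Couple top-of-canopy reflectance to top-of-atmosphere
#'
#' Applies the Lambertian coupling
#' `rho_toa = Tgas * (rho0 + Tdwn * Tup * rho / (1 - S * rho))`
#' and the radiance form `L = I0 * cos(theta_il) / pi * rho_toa`.
#' The multiple-scattering denominator is guarded: `1 - S * rho` must stay
#' above `1e-6` everywhere.
#'
#' @param rho top-of-canopy reflectance [vt_spectrum].
#' @param tf [transfer_functions] on the same wavelength grid.
#' @param theta_il solar zenith angle (degrees).
#' @return A list with `radiance` (a radiance [vt_spectrum], units of `I0`
#'   per steradian) and `rho_toa` (a reflectance [vt_spectrum]).
#' @export
couple_to_toa <- function(rho, tf, theta_il) {
  stopifnot(inherits(rho, "vt_spectrum"), inherits(tf, "transfer_functions"))
  if (length(rho$wavelengths) != length(tf$wavelengths) ||
      any(abs(rho$wavelengths - tf$wavelengths) > 1e-9)) {
    stop("TOC spectrum and transfer functions are on different grids",
         call. = FALSE)
  }
  denom <- 1 - tf$s * rho$values
  if (any(denom < 1e-6)) {
    bad <- rho$wavelengths[denom < 1e-6]
    stop(sprintf(
      "multiple-scattering series diverges (1 - S*rho < 1e-6) at %d wavelengths, e.g. %.1f nm",
      length(bad), bad[1]), call. = FALSE)
  }
  rho_toa <- tf$tgas * (tf$rho0 + tf$tdwn * tf$tup * rho$values / denom)
  mu_il <- cos(theta_il * pi / 180)
  L <- tf$i0 * mu_il / pi * rho_toa
  list(radiance = vt_spectrum(rho$wavelengths, L, "radiance"),
       rho_toa = vt_spectrum(rho$wavelengths, pmin(rho_toa, 1),
                             "reflectance"))
}

## ---- LUT adapter ------------------------------------------------------------

lut_state_vars <- c("O3C", "CWV", "AOT", "ALPHA", "G")
lut_fun_cols <- c("rho0", "tgas", "tdwn", "tup", "s", "i0")

#' Write an atmospheric transfer-function look-up table
#'
#' Delimited-text LUT with one row per (atmosphere state, wavelength):
#' columns `O3C, CWV, AOT, ALPHA, G, wavelength, rho0, tgas, tdwn, tup, s,
#' i0`. Compatible with tables exported from external atmospheric RTM runs.
#'
#' @param states list of [atmosphere_state] objects.
#' @param tfs list of [transfer_functions], one per state, on a shared grid.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_atmosphere_lut <- function(states, tfs, path) {
  stopifnot(length(states) == length(tfs), length(states) >= 1L)
  rows <- lapply(seq_along(states), function(i) {
    st <- states[[i]]
    tf <- tfs[[i]]
    data.frame(O3C = st$O3C, CWV = st$CWV, AOT = st$AOT, ALPHA = st$ALPHA,
               G = st$G, wavelength = tf$wavelengths,
               rho0 = tf$rho0, tgas = tf$tgas, tdwn = tf$tdwn,
               tup = tf$tup, s = tf$s, i0 = tf$i0)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read an atmospheric transfer-function look-up table
#'
#' @param path a file written by [write_atmosphere_lut] (or exported from an
#'   external atmospheric RTM in the same grammar).
#' @return A `lut` object for [simulate_transfer_functions].
#' @export
read_atmosphere_lut <- function(path) {
  tab <- utils::read.csv(path)
  need <- c(lut_state_vars, "wavelength", lut_fun_cols)
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("malformed LUT file; missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  key <- do.call(paste, c(tab[lut_state_vars], sep = "|"))
  nodes <- unique(tab[!duplicated(key), lut_state_vars, drop = FALSE])
  grid <- sort(unique(tab$wavelength))
  structure(list(table = tab, nodes = nodes, grid = grid, key = key),
            class = "atmosphere_lut")
}

# Inverse-distance (Shepard) interpolation over the normalized state space;
# exact at nodes, refuses queries outside the per-variable hull.
interpolate_atmosphere_lut <- function(lut, state, grid) {
  q <- unlist(state[lut_state_vars])
  lo <- vapply(lut$nodes, min, numeric(1))
  hi <- vapply(lut$nodes, max, numeric(1))
  out_of_hull <- q < lo - 1e-12 | q > hi + 1e-12
  if (any(out_of_hull)) {
    stop("LUT extrapolation error for variable(s): ",
         paste(lut_state_vars[out_of_hull], collapse = ", "), call. = FALSE)
  }
  scale <- pmax(hi - lo, 1e-12)
  nodes_n <- sweep(sweep(as.matrix(lut$nodes), 2, lo), 2, scale, "/")
  qn <- (q - lo) / scale
  d2 <- rowSums(sweep(nodes_n, 2, qn)^2)
  if (min(d2) < 1e-20) {
    w <- as.numeric(d2 < 1e-20)
  } else {
    w <- 1 / d2
  }
  w <- w / sum(w)
  node_key <- do.call(paste, c(lut$nodes, sep = "|"))
  fun_mats <- lapply(lut_fun_cols, function(col) {
    vapply(node_key, function(k) {
      sub <- lut$table[lut$key == k, c("wavelength", col)]
      sub <- sub[order(sub$wavelength), ]
      if (min(grid) < min(sub$wavelength) || max(grid) > max(sub$wavelength)) {
        stop("requested grid outside LUT wavelength support", call. = FALSE)
      }
      stats::splinefun(sub$wavelength, sub[[col]], method = "fmm")(grid)
    }, numeric(length(grid)))
  })
  names(fun_mats) <- lut_fun_cols
  mix <- lapply(fun_mats, function(m) as.numeric(m %*% w))
  transfer_functions(grid, rho0 = pmax(mix$rho0, 0),
                     tgas = pmin(pmax(mix$tgas, 0), 1),
                     tdwn = pmin(pmax(mix$tdwn, 0), 1),
                     tup = pmin(pmax(mix$tup, 0), 1),
                     s = pmin(pmax(mix$s, 0), 0.999),
                     i0 = pmax(mix$i0, 1e-6))
}
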