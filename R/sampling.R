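#' Sampling specification for the simulation variables
#'
#' A sampling spec is a list of per-variable entries
#' `list(name, unit, range = c(lo, hi) | value, distribution)` with
#' distribution one of `"uniform"`, `"gaussian"` (with `mean` and `sd`,
#' truncated to the range by rejection), `"lhs"` (Latin hypercube,
#' stratified jointly across all lhs variables) or `"fixed"`.
#'
#' `default_canopy_spec()` fixes the reference configuration for the leaf
#' and canopy variables (structure parameter uniform 1.3-2.5, chlorophyll
#' Gaussian mean 35 sd 30 on 5-75 ug/cm2, dry matter Gaussian mean 0.005 sd
#' 0.001 on 0.001-0.03 g/cm2, water Gaussian mean 0.02 sd 0.01 on
#' 0.002-0.05 cm, LAI Gaussian mean 3 sd 2 on 0.1-7, soil brightness
#' uniform 0-1, average leaf angle uniform 40-70 deg, hot spot 0.01, diffuse
#' fraction 0.05, sun zenith uniform 20-30 deg, nadir view). Fractional
#' vegetation cover is never sampled: it is derived from the gap fraction.
#'
#' @return A list of class `sampling_spec`.
#' @export
default_canopy_spec <- function() {
  spec <- list(
    list(name = "N", unit = "unitless", range = c(1.3, 2.5),
         distribution = "uniform"),
    list(name = "Cab", unit = "ug/cm2", range = c(5, 75),
         distribution = "gaussian", mean = 35, sd = 30),
    list(name = "Cm", unit = "g/cm2", range = c(0.001, 0.03),
         distribution = "gaussian", mean = 0.005, sd = 0.001),
    list(name = "Cw", unit = "cm", range = c(0.002, 0.05),
         distribution = "gaussian", mean = 0.02, sd = 0.01),
    list(name = "LAI", unit = "m2/m2", range = c(0.1, 7),
         distribution = "gaussian", mean = 3, sd = 2),
    list(name = "alpha_soil", unit = "unitless", range = c(0, 1),
         distribution = "uniform"),
    list(name = "ALA", unit = "deg", range = c(40, 70),
         distribution = "uniform"),
    list(name = "HotS", unit = "m/m", value = 0.01, distribution = "fixed"),
    list(name = "skyl", unit = "fraction", value = 0.05,
         distribution = "fixed"),
    list(name = "theta_s", unit = "deg", range = c(20, 30),
         distribution = "uniform"),
    list(name = "theta_v", unit = "deg", value = 0, distribution = "fixed"),
    list(name = "phi", unit = "deg", value = 0, distribution = "fixed")
  )
  structure(spec, class = "sampling_spec")
}

#' @rdname default_canopy_spec
#' @details `default_atmosphere_spec()` covers the atmospheric variables:
#'   ozone column 0.25-0.35 atm-cm, columnar water vapour 0.4-4.5 g/cm2,
#'   aerosol optical thickness 0.05-0.5, Angstrom coefficient 0.05-2 and
#'   asymmetry factor 0.6-1, all Latin-hypercube sampled, plus solar zenith
#'   uniform 20-30 deg.
#' @export
default_atmosphere_spec <- function() {
  spec <- list(
    list(name = "O3C", unit = "atm-cm", range = c(0.25, 0.35),
         distribution = "lhs"),
    list(name = "CWV", unit = "g/cm2", range = c(0.4, 4.5),
         distribution = "lhs"),
    list(name = "AOT", unit = "unitless", range = c(0.05, 0.5),
         distribution = "lhs"),
    list(name = "ALPHA", unit = "unitless", range = c(0.05, 2),
         distribution = "lhs"),
    list(name = "G", unit = "unitless", range = c(0.6, 0.999),
         distribution = "lhs"),
    list(name = "theta_il", unit = "deg", range = c(20, 30),
         distribution = "uniform")
  )
  structure(spec, class = "sampling_spec")
}

validate_spec_entry <- function(e) {
  if (is.null(e$name) || is.null(e$distribution)) {
    stop("sampling spec entry needs 'name' and 'distribution'", call. = FALSE)
  }
  d <- e$distribution
  if (!d %in% c("uniform", "gaussian", "lhs", "fixed")) {
    stop(sprintf("variable '%s': unknown distribution '%s'", e$name, d),
         call. = FALSE)
  }
  if (d == "fixed") {
    if (is.null(e$value)) stop(sprintf("fixed variable '%s' needs a value",
                                       e$name), call. = FALSE)
  } else {
    if (is.null(e$range) || length(e$range) != 2L ||
        e$range[1] >= e$range[2]) {
      stop(sprintf("variable '%s' needs a range c(lo, hi) with lo < hi",
                   e$name), call. = FALSE)
    }
    if (d == "gaussian" && (is.null(e$mean) || is.null(e$sd) || e$sd <= 0)) {
      stop(sprintf("gaussian variable '%s' needs mean and positive sd",
                   e$name), call. = FALSE)
    }
  }
  invisible(e)
}

# truncated normal by rejection (no clipping, so no mass spikes at the edges)
rtruncnorm_reject <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(max(2L * (n - length(out)), 16L), mean, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

#' Draw a parameter table from a sampling specification
#'
#' Uniform variables are drawn independently within their range; Gaussian
#' variables are truncated to their range by rejection sampling; all `lhs`
#' variables are drawn jointly by Latin hypercube (exactly one draw per
#' equal-probability stratum per variable); fixed variables are constant.
#'
#' @param spec a `sampling_spec`.
#' @param n number of rows (>= 1).
#' @param seed integer seed; the draw is fully reproducible.
#' @return A data.frame with one column per variable and `n` rows.
#' @export
sample_parameters <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "sampling_spec") || is.list(spec), n >= 1)
  lapply(spec, validate_spec_entry)
  names(spec) <- vapply(spec, `[[`, character(1), "name")
  lhs_vars <- names(spec)[vapply(spec, function(e)
    e$distribution == "lhs", logical(1))]
  with_seed(seed, {
    cols <- list()
    if (length(lhs_vars)) {
      cube <- lhs::randomLHS(n, length(lhs_vars))
      colnames(cube) <- lhs_vars
    }
    for (e in spec) {
      cols[[e$name]] <- switch(
        e$distribution,
        uniform = stats::runif(n, e$range[1], e$range[2]),
        gaussian = rtruncnorm_reject(n, e$mean, e$sd, e$range[1], e$range[2]),
        lhs = e$range[1] + cube[, e$name] * (e$range[2] - e$range[1]),
        fixed = rep(e$value, n)
      )
    }
    as.data.frame(cols)
  })
}
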