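test_that("transfer function invariants are enforced", {
  g <- 400:410
  ok <- transfer_functions(g, rho0 = rep(0.05, 11), tgas = rep(0.9, 11),
                           tdwn = rep(0.8, 11), tup = rep(0.85, 11),
                           s = rep(0.1, 11), i0 = rep(1800, 11))
  expect_s3_class(ok, "transfer_functions")
  expect_error(transfer_functions(g, rep(0.05, 11), rep(1.2, 11),
                                  rep(0.8, 11), rep(0.8, 11), rep(0.1, 11),
                                  rep(1800, 11)), "tgas")
  expect_error(transfer_functions(g, rep(0.05, 11), rep(0.9, 11),
                                  rep(0.8, 11), rep(0.8, 11), rep(1, 11),
                                  rep(1800, 11)), "spherical albedo")
})

test_that("parametric atmosphere responds sign-correctly to its drivers", {
  grid <- seq(400, 2500, 2.5)
  base <- atmosphere_state(AOT = 0, CWV = 0, O3C = 0, G = 0.8)
  tf0 <- simulate_transfer_functions(base, grid)
  # no absorbers: full gas transmittance, Rayleigh-only path reflectance
  expect_equal(max(abs(tf0$tgas - 1)), 0)
  expect_true(all(tf0$rho0 > 0))
  expect_true(all(tf0$s > 0 & tf0$s < 0.3))
  # spherical albedo falls off steeply with wavelength (Rayleigh-dominated)
  expect_lt(tf0$s[length(tf0$s)], 0.01)
  i493 <- which.min(abs(grid - 493))
  # increasing aerosol load strictly decreases the two-way scattering
  # transmittance in the blue
  tf_a <- simulate_transfer_functions(atmosphere_state(AOT = 0.4, CWV = 0,
                                                       O3C = 0), grid)
  expect_lt(tf_a$tdwn[i493] * tf_a$tup[i493], tf0$tdwn[i493] * tf0$tup[i493])
  # water vapour eats into the 940 nm band but leaves the green untouched
  i940 <- which.min(abs(grid - 940))
  i560 <- which.min(abs(grid - 560))
  tf_w1 <- simulate_transfer_functions(atmosphere_state(CWV = 0.5), grid)
  tf_w2 <- simulate_transfer_functions(atmosphere_state(CWV = 4.5), grid)
  expect_lt(tf_w2$tgas[i940], tf_w1$tgas[i940])
  expect_equal(tf_w2$tgas[i560], tf_w1$tgas[i560], tolerance = 1e-6)
})

test_that("TOA coupling satisfies its limiting identities", {
  grid <- seq(400, 900, 10)
  n <- length(grid)
  rho <- vt_spectrum(grid, seq(0.05, 0.6, length.out = n), "reflectance")
  ident <- transfer_functions(grid, rho0 = rep(0, n), tgas = rep(1, n),
                              tdwn = rep(1, n), tup = rep(1, n),
                              s = rep(0, n), i0 = rep(pi, n))
  out <- couple_to_toa(rho, ident, theta_il = 0)
  # transparent atmosphere: TOA reflectance equals the surface reflectance,
  # and with I0 = pi at overhead sun the radiance equals it numerically
  expect_equal(out$rho_toa$values, rho$values)
  expect_equal(out$radiance$values, rho$values)
  # black surface: only the path signal Tgas * rho0 remains
  tf <- transfer_functions(grid, rho0 = rep(0.05, n), tgas = rep(0.9, n),
                           tdwn = rep(0.8, n), tup = rep(0.8, n),
                           s = rep(0.1, n), i0 = rep(1700, n))
  black <- vt_spectrum(grid, rep(0, n), "reflectance")
  expect_equal(couple_to_toa(black, tf, 20)$rho_toa$values,
               rep(0.9 * 0.05, n))
})

test_that("TOA coupling matches hand arithmetic and round-trips radiance", {
  grid <- c(500, 600)
  tf <- transfer_functions(grid, rho0 = c(0.05, 0.05), tgas = c(0.9, 0.9),
                           tdwn = c(0.8, 0.8), tup = c(0.8, 0.8),
                           s = c(0.1, 0.1), i0 = c(1800, 1700))
  rho <- vt_spectrum(grid, c(0.5, 0.5), "reflectance")
  out <- couple_to_toa(rho, tf, theta_il = 30)
  hand <- 0.9 * (0.05 + 0.8 * 0.8 * 0.5 / (1 - 0.1 * 0.5))
  expect_equal(out$rho_toa$values, rep(hand, 2))
  # reflectance recovered from radiance to machine precision
  back <- pi * out$radiance$values / (tf$i0 * cos(30 * pi / 180))
  expect_equal(back, out$rho_toa$values, tolerance = 1e-14)
})

test_that("spherical albedo drives the multiple-scattering enhancement", {
  grid <- c(550, 850)
  rho <- vt_spectrum(grid, c(0.4, 0.4), "reflectance")
  mk <- function(s) transfer_functions(grid, rho0 = c(0.02, 0.02),
                                       tgas = c(1, 1), tdwn = c(0.9, 0.9),
                                       tup = c(0.9, 0.9), s = rep(s, 2),
                                       i0 = c(1800, 1000))
  single_bounce <- 1 * (0.02 + 0.9 * 0.9 * 0.4)
  prev <- 0
  for (s in c(0, 0.1, 0.2, 0.3)) {
    val <- couple_to_toa(rho, mk(s), 25)$rho_toa$values[1]
    if (s == 0) expect_equal(val, single_bounce)
    expect_gte(val, prev)
    prev <- val
  }
  # monotone increase of rho_toa in surface reflectance
  vals <- vapply(seq(0, 0.9, 0.1), function(r) {
    couple_to_toa(vt_spectrum(grid, rep(r, 2), "reflectance"),
                  mk(0.2), 25)$rho_toa$values[1]
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("coupling guards grids and the geometric-series divergence", {
  tf <- transfer_functions(c(500, 600), rho0 = c(0, 0), tgas = c(1, 1),
                           tdwn = c(1, 1), tup = c(1, 1),
                           s = c(0.9999995, 0), i0 = c(1, 1))
  rho_bad <- vt_spectrum(c(500, 600), c(1, 0.5), "reflectance")
  expect_error(couple_to_toa(rho_bad, tf, 0), "diverges")
  rho_off <- vt_spectrum(c(500, 601), c(0.5, 0.5), "reflectance")
  expect_error(couple_to_toa(rho_off, tf, 0), "different grids")
})

test_that("atmosphere LUT adapter round-trips node values exactly", {
  grid <- seq(400, 1000, 100)
  n <- length(grid)
  st1 <- atmosphere_state(O3C = 0.25, CWV = 1, AOT = 0.1, ALPHA = 0.5,
                          G = 0.7)
  st2 <- atmosphere_state(O3C = 0.35, CWV = 4, AOT = 0.5, ALPHA = 1.8,
                          G = 0.9)
  tf1 <- simulate_transfer_functions(st1, grid)
  tf2 <- simulate_transfer_functions(st2, grid)
  path <- tempfile(fileext = ".csv")
  write_atmosphere_lut(list(st1, st2), list(tf1, tf2), path)
  lut <- read_atmosphere_lut(path)
  got <- simulate_transfer_functions(st1, grid, provider = "lut-adapter",
                                     lut = lut)
  expect_equal(got$tgas, tf1$tgas, tolerance = 1e-9)
  expect_equal(got$rho0, tf1$rho0, tolerance = 1e-9)
  # outside the node hull the adapter refuses to extrapolate
  st_out <- atmosphere_state(O3C = 0.5, CWV = 1, AOT = 0.1, ALPHA = 0.5,
                             G = 0.7)
  expect_error(simulate_transfer_functions(st_out, grid, "lut-adapter",
                                           lut = lut), "extrapolation")
  # malformed files are named as such
  bad <- tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_error(read_atmosphere_lut(bad), "missing columns")
})
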