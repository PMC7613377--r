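# Generates the frozen plain-text basis tables shipped in inst/extdata/.
# Run from the package root: Rscript data-raw/basis_curves.R
# The CSVs are the single source of truth; the package only reads them.

gauss <- function(lambda, centre, width) exp(-0.5 * ((lambda - centre) / width)^2)

wl <- seq(400, 2500, by = 5)

## --- surrogate canopy basis -------------------------------------------------
# soil: dry-soil brightening ramp with shallow water dips; scaled by alpha_soil
soil <- 0.10 + 0.22 * (1 - exp(-(wl - 400) / 900)) -
  0.020 * gauss(wl, 1940, 60) - 0.015 * gauss(wl, 1450, 45)
soil <- pmax(soil, 0)

# leaf: green bump + red-edge logistic to an NIR plateau decaying through SWIR
leaf <- 0.03 + 0.08 * gauss(wl, 550, 40) +
  0.46 * plogis((wl - 718) / 16) * (1 - 0.35 * plogis((wl - 1350) / 250))

# specific absorption shapes (Beer-Lambert exponents per unit trait)
a_cab <- 0.045 * (gauss(wl, 672, 40) + 0.8 * gauss(wl, 480, 45))   # per ug/cm2
a_w <- 120 * gauss(wl, 1940, 70) + 32 * gauss(wl, 1450, 55) +      # per cm EWT
  7 * gauss(wl, 1650, 120) + 45 * gauss(wl, 2700, 250) +
  2.5 * gauss(wl, 1190, 60) + 1.2 * gauss(wl, 970, 45)
a_m <- 15 * gauss(wl, 2100, 150) + 10 * gauss(wl, 1720, 90) +      # per g/cm2
  8 * gauss(wl, 2300, 120)

write.csv(
  data.frame(wavelength = wl,
             soil = round(soil, 6), leaf = round(leaf, 6),
             a_cab = round(a_cab, 6), a_w = round(a_w, 5),
             a_m = round(a_m, 5)),
  "inst/extdata/surrogate_basis.csv", row.names = FALSE, quote = FALSE)

## --- parametric atmosphere basis --------------------------------------------
# ozone Chappuis-like band; water-vapour band complex; smooth solar curve
a_o3 <- 0.10 * gauss(wl, 600, 60)                                   # per atm-cm
a_h2o <- 0.012 * gauss(wl, 720, 15) + 0.030 * gauss(wl, 820, 18) +  # per (g/cm2)^b
  0.25 * gauss(wl, 940, 25) + 0.45 * gauss(wl, 1130, 30) +
  2.6 * gauss(wl, 1380, 40) + 1.9 * gauss(wl, 1870, 45) +
  0.35 * gauss(wl, 2500, 120)
# extraterrestrial solar irradiance, mW m-2 nm-1: Planck 5800 K shape scaled
# so that E0(550 nm) = 1900 mW m-2 nm-1
planck <- function(lam_nm, temp) {
  lam <- lam_nm * 1e-9
  h <- 6.62607015e-34; c <- 2.99792458e8; kb <- 1.380649e-23
  lam^-5 / (exp(h * c / (lam * kb * temp)) - 1)
}
e0 <- planck(wl, 5800) / planck(550, 5800) * 1900

write.csv(
  data.frame(wavelength = wl,
             a_o3 = round(a_o3, 6), a_h2o = round(a_h2o, 6),
             e0 = round(e0, 3)),
  "inst/extdata/atmosphere_basis.csv", row.names = FALSE, quote = FALSE)

cat("wrote inst/extdata/{surrogate_basis,atmosphere_basis}.csv\n")
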