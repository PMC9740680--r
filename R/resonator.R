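# Physics of the liquid-loaded quartz crystal resonator: the Kanazawa-Gordon
# frequency-shift model, its viscosity inversion, and an idealized Lorentzian
# conductance curve used to exercise the sweep-processing stage.

#' Physical constants of the quartz resonator
#'
#' Bundles the fixed parameters of an AT-cut quartz crystal operated at its
#' fundamental: resonance frequency `f0`, quartz density `rho_q`, quartz
#' shear modulus `G_q`, and the (odd) overtone number `n`.
#'
#' @param f0 Fundamental resonance frequency in Hz.
#' @param rho_q Quartz density in kg m^-3.
#' @param G_q Quartz shear modulus in N m^-2.
#' @param n Overtone number; must be an odd positive integer.
#' @return An object of class `quartz_constants`.
#' @export
#' @examples
#' quartz_constants() # the 10 MHz crystal used throughout
quartz_constants <- function(f0 = 1.0e7, rho_q = 2648, G_q = 2.947e10, n = 1L) {
  if (!all(vapply(list(f0, rho_q, G_q, n), function(x)
    is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0, logical(1)))) {
    stop("all quartz constants must be single positive finite numbers")
  }
  if (n != floor(n) || n %% 2 != 1) {
    stop("overtone number `n` must be an odd positive integer")
  }
  structure(list(f0 = f0, rho_q = rho_q, G_q = G_q, n = as.integer(n)),
            class = "quartz_constants")
}

#' Newtonian liquid load on the resonator
#'
#' Describes the fluid in contact with the crystal by its density and dynamic
#' viscosity, plus the dimensionless viscoelastic ratio
#' \eqn{\Delta\Gamma / |\Delta f|}. The ratio is 1 for an ideal Newtonian
#' semi-infinite liquid; synovial fluid measured with this sensor shows a
#' ratio near 0.49.
#'
#' @param rho_L Fluid density in kg m^-3.
#' @param eta_L Dynamic viscosity in Pa s.
#' @param viscoelastic_ratio Positive dimensionless ratio
#'   \eqn{\Delta\Gamma / |\Delta f|} (default 1, Newtonian).
#' @return An object of class `liquid_load`.
#' @export
liquid_load <- function(rho_L, eta_L, viscoelastic_ratio = 1) {
  for (v in c(rho_L = rho_L, eta_L = eta_L, viscoelastic_ratio = viscoelastic_ratio)) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop("liquid load parameters must be single positive finite numbers")
    }
  }
  structure(list(rho_L = rho_L, eta_L = eta_L,
                 viscoelastic_ratio = viscoelastic_ratio),
            class = "liquid_load")
}

#' Calibrated synovial fluid density
#'
#' Density (kg m^-3) assumed when converting a measured frequency shift into
#' a viscosity. The value is the single density that reconciles the
#' EDTA-tube inflammatory class means (frequency shift -3665.36 Hz and
#' viscosity 3.46 mPa s) under the Kanazawa-Gordon relation for the 10 MHz
#' crystal; no single density reconciles all four class/tube mean pairs
#' (implied densities span roughly 929-971 kg m^-3), so this constant is a
#' calibration choice and is exposed as a parameter wherever it is used.
#'
#' @format A single numeric value, 951.93.
#' @export
synovial_density <- 951.93

#' Kanazawa-Gordon frequency shift of a liquid-loaded crystal
#'
#' For a Newtonian semi-infinite liquid the series resonance frequency drops
#' by
#' \deqn{\Delta f = -\, n f_0^{3/2} \sqrt{\rho_L \eta_L / (\pi \rho_q G_q)},}
#' i.e. proportionally to the square root of the density-viscosity product.
#'
#' @param load A [liquid_load()].
#' @param quartz A [quartz_constants()].
#' @return Frequency shift in Hz (strictly negative).
#' @export
#' @examples
#' # water on a 10 MHz crystal: about -2 kHz
#' kanazawa_frequency_shift(liquid_load(1000, 1e-3), quartz_constants())
kanazawa_frequency_shift <- function(load, quartz = quartz_constants()) {
  stopifnot(inherits(load, "liquid_load"), inherits(quartz, "quartz_constants"))
  -quartz$n * quartz$f0^1.5 *
    sqrt(load$rho_L * load$eta_L / (pi * quartz$rho_q * quartz$G_q))
}

#' Invert the Kanazawa-Gordon relation for viscosity
#'
#' Solves the frequency-shift relation for the dynamic viscosity:
#' \deqn{\eta_L = \Delta f^2 \, \pi \rho_q G_q / (n^2 f_0^3 \rho_L).}
#' The assumed fluid density must be supplied; see [synovial_density] for
#' the calibrated default used for synovial fluid.
#'
#' @param delta_f Frequency shift in Hz; must be nonzero.
#' @param rho_L Assumed fluid density in kg m^-3.
#' @param quartz A [quartz_constants()].
#' @return Dynamic viscosity in Pa s.
#' @export
#' @examples
#' invert_viscosity(-2019.65, rho_L = 1000) # ~1e-3 Pa s (water)
invert_viscosity <- function(delta_f, rho_L = synovial_density,
                             quartz = quartz_constants()) {
  stopifnot(inherits(quartz, "quartz_constants"))
  if (!is.numeric(delta_f) || any(!is.finite(delta_f)) || any(delta_f == 0)) {
    stop("`delta_f` must be finite and nonzero")
  }
  if (!is.numeric(rho_L) || length(rho_L) != 1 || !is.finite(rho_L) || rho_L <= 0) {
    stop("`rho_L` must be a single positive density")
  }
  delta_f^2 * pi * quartz$rho_q * quartz$G_q /
    (quartz$n^2 * quartz$f0^3 * rho_L)
}

#' Expected half-bandwidth shift for a liquid load
#'
#' Models the dissipation response as proportional to the magnitude of the
#' frequency shift, \eqn{\Delta\Gamma = r \, |\Delta f|}, where `r` is the
#' load's viscoelastic ratio. For an ideal Newtonian liquid (`r = 1`) the
#' half-bandwidth shift equals \eqn{-\Delta f} exactly.
#'
#' @inheritParams kanazawa_frequency_shift
#' @return Half-bandwidth shift in Hz (positive).
#' @export
expected_bandwidth_shift <- function(load, quartz = quartz_constants()) {
  load$viscoelastic_ratio * abs(kanazawa_frequency_shift(load, quartz))
}

#' Conductance sweep container
#'
#' One acquisition: conductance measured over a strictly increasing
#' frequency grid, tagged as the unloaded (`"air"`) or loaded reference.
#'
#' @param frequencies Strictly increasing numeric frequency grid in Hz,
#'   length at least 3.
#' @param conductance Nonnegative finite conductance values in S, same
#'   length as `frequencies`.
#' @param condition `"air"` or `"loaded"`.
#' @return An object of class `conductance_sweep`.
#' @export
conductance_sweep <- function(frequencies, conductance,
                              condition = c("loaded", "air")) {
  condition <- match.arg(condition)
  if (length(frequencies) < 3 || length(conductance) != length(frequencies)) {
    stop("sweep needs >= 3 points and equal-length frequency/conductance vectors")
  }
  if (any(!is.finite(frequencies)) || any(diff(frequencies) <= 0)) {
    stop("`frequencies` must be finite and strictly increasing")
  }
  if (any(!is.finite(conductance)) || any(conductance < 0)) {
    stop("`conductance` must be finite and nonnegative")
  }
  structure(list(frequencies = frequencies, conductance = conductance,
                 condition = condition),
            class = "conductance_sweep")
}

#' Simulate a near-resonance conductance sweep
#'
#' Generates the Lorentzian conductance curve of a series resonant branch,
#' \deqn{G(f) = G_{max} / (1 + ((f - f_s)/\Gamma)^2),}
#' optionally perturbed by multiplicative Gaussian noise. The grid must
#' cover both half-maximum crossings \eqn{f_s \pm \Gamma}, otherwise the
#' half-bandwidth would be inestimable downstream.
#'
#' @param fs Series resonance frequency in Hz.
#' @param gamma Half-bandwidth at half-maximum in Hz (> 0).
#' @param g_max Peak conductance in S (> 0).
#' @param grid Strictly increasing frequency grid in Hz; should span at
#'   least `fs +/- 3 * gamma`.
#' @param noise_sd Relative (multiplicative) noise standard deviation;
#'   0 gives the noiseless curve. Negative excursions are clipped at 0.
#' @param condition Sweep tag, `"loaded"` or `"air"`.
#' @param seed Optional integer seed for the noise draw.
#' @return A [conductance_sweep()].
#' @export
#' @examples
#' grid <- seq(9.98e6, 10.02e6, length.out = 501)
#' sw <- simulate_sweep(1e7, 1800, 1e-3, grid)
simulate_sweep <- function(fs, gamma, g_max, grid, noise_sd = 0,
                           condition = "loaded", seed = NULL) {
  stopifnot(is.numeric(fs), length(fs) == 1, is.finite(fs))
  if (!is.numeric(gamma) || length(gamma) != 1 || !is.finite(gamma) || gamma <= 0) {
    stop("`gamma` must be a single positive half-bandwidth")
  }
  if (!is.numeric(g_max) || length(g_max) != 1 || g_max <= 0) {
    stop("`g_max` must be positive")
  }
  if (min(grid) > fs - gamma || max(grid) < fs + gamma) {
    stop("frequency grid does not cover the half-maximum crossings fs +/- gamma")
  }
  g <- g_max / (1 + ((grid - fs) / gamma)^2)
  if (noise_sd > 0) {
    g <- with_seed(seed, g * (1 + stats::rnorm(length(g), sd = noise_sd)))
    g <- pmax(g, 0)
  }
  conductance_sweep(grid, g, condition)
}
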