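#' Default eight-wavelength LED set (nm)
#'
#' The transmissive finger probe uses eight LEDs spanning the red to
#' near-infrared window where oxy- and deoxyhemoglobin absorption differ
#' enough to separate the two species.
#'
#' @export
HEMOPPG_WAVELENGTHS <- c(610, 630, 660, 690, 750, 805, 850, 940)

# Oxy-/deoxyhemoglobin molar extinction coefficients at the eight LED
# wavelengths, from standard literature compilations of hemoglobin spectra.
# Units are arbitrary-but-consistent (per concentration per length); only
# their ratios and products with Delta<L> enter the model, so any consistent
# pair works. These are configuration defaults, not measured data.
.default_ext_oxy   <- c(1092.0, 610.0, 319.6, 276.0, 518.0, 816.0, 1058.0, 1214.0)
.default_ext_deoxy <- c(9443.0, 5148.8, 3226.6, 2407.9, 1405.2, 761.8, 691.3, 693.4)

#' Optical configuration of the simulated acquisition system
#'
#' Bundles everything the Beer-Lambert forward model needs: the LED
#' wavelengths, molar extinction coefficients of oxygenated and reduced
#' hemoglobin at each wavelength, the static (non-pulsatile) tissue
#' absorbance per wavelength, the fractional optical path-length change per
#' cardiac pulse (Delta<L>), and the incident intensity I0.
#'
#' @param wavelengths numeric vector of exactly 8 strictly increasing
#'   wavelengths in nm.
#' @param ext_oxy,ext_deoxy positive extinction coefficients of oxy- and
#'   deoxyhemoglobin at each wavelength (consistent units).
#' @param baseline_absorbance static tissue absorbance per wavelength
#'   (dimensionless optical density); sets the DC light level.
#' @param path_pulse_amplitude Delta<L>, the pulsatile optical path change
#'   per beat, in units consistent with `ext_*` and concentration in g/dL.
#'   The default yields perfusion indices of roughly 2-6% across channels.
#' @param incident_intensity I0, incident light intensity (arbitrary units).
#'
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(wavelengths = HEMOPPG_WAVELENGTHS,
                           ext_oxy = .default_ext_oxy,
                           ext_deoxy = .default_ext_deoxy,
                           baseline_absorbance = rep(0.5, 8),
                           path_pulse_amplitude = 3e-6,
                           incident_intensity = 1.0) {
  stopifnot(length(wavelengths) == 8)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  stopifnot(
    length(ext_oxy) == 8, length(ext_deoxy) == 8,
    length(baseline_absorbance) == 8,
    all(ext_oxy > 0), all(ext_deoxy > 0),
    path_pulse_amplitude > 0, incident_intensity > 0
  )
  structure(
    list(
      wavelengths = as.numeric(wavelengths),
      ext_oxy = as.numeric(ext_oxy),
      ext_deoxy = as.numeric(ext_deoxy),
      baseline_absorbance = as.numeric(baseline_absorbance),
      path_pulse_amplitude = path_pulse_amplitude,
      incident_intensity = incident_intensity
    ),
    class = "optical_config"
  )
}

#' Physiological state of one simulated subject
#'
#' @param hb_total total hemoglobin concentration c_tHb in g/dL, in (4, 22).
#' @param spo2 arterial oxygen saturation as a fraction in [0.7, 1].
#'   Oxygenated Hb is c1 = spo2 * hb_total and reduced Hb is
#'   c2 = (1 - spo2) * hb_total, so c1 + c2 = hb_total.
#' @param heart_rate beats per minute, in [40, 180].
#' @param resp_rate respiratory rate in Hz (drives baseline wander).
#'
#' @return An object of class `physio_state` with derived fields `c1`, `c2`.
#' @export
physio_state <- function(hb_total = 14, spo2 = 0.97,
                         heart_rate = 72, resp_rate = 0.25) {
  if (!(hb_total > 4 && hb_total < 22))
    stop("hb_total must lie in (4, 22) g/dL")
  if (!(spo2 >= 0.7 && spo2 <= 1.0))
    stop("spo2 must lie in [0.7, 1.0]")
  if (!(heart_rate >= 40 && heart_rate <= 180))
    stop("heart_rate must lie in [40, 180] bpm")
  stopifnot(resp_rate > 0)
  structure(
    list(
      hb_total = hb_total, spo2 = spo2,
      heart_rate = heart_rate, resp_rate = resp_rate,
      c1 = spo2 * hb_total, c2 = (1 - spo2) * hb_total
    ),
    class = "physio_state"
  )
}

#' Noise and artifact configuration for the PPG simulator
#'
#' Emulates the disturbances a finger-clip acquisition sees: broadband
#' electronic noise, respiratory baseline wander, mains interference, and
#' occasional motion transients. All amplitudes are relative to the channel
#' DC level.
#'
#' @param white_sd SD of additive white Gaussian noise (fraction of DC).
#' @param drift_amp,drift_freq baseline-wander sinusoid amplitude (fraction
#'   of DC) and frequency (Hz, must be < 0.5).
#' @param powerline_amp,powerline_freq mains tone amplitude (fraction of DC)
#'   and frequency in Hz.
#' @param motion_prob probability that any given 5 s stretch contains a
#'   motion transient.
#' @param motion_amp amplitude of a motion transient (fraction of DC).
#'
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(white_sd = 0.003,
                         drift_amp = 0.05, drift_freq = 0.25,
                         powerline_amp = 0.01, powerline_freq = 50,
                         motion_prob = 0.03, motion_amp = 0.05) {
  stopifnot(
    white_sd >= 0, drift_amp >= 0, powerline_amp >= 0,
    motion_prob >= 0, motion_prob <= 1, motion_amp >= 0,
    drift_freq > 0, powerline_freq > 0
  )
  if (drift_freq >= 0.5) stop("drift_freq must be < 0.5 Hz")
  structure(
    list(
      white_sd = white_sd,
      drift_amp = drift_amp, drift_freq = drift_freq,
      powerline_amp = powerline_amp, powerline_freq = powerline_freq,
      motion_prob = motion_prob, motion_amp = motion_amp
    ),
    class = "noise_config"
  )
}

#' Noise-free configuration (all disturbance amplitudes zero)
#'
#' @return A `noise_config` with every amplitude set to 0.
#' @export
noise_off <- function() {
  noise_config(white_sd = 0, drift_amp = 0, powerline_amp = 0,
               motion_prob = 0, motion_amp = 0)
}

# Effective pulsatile extinction at each wavelength for a physiological
# state: eps_oxy * c1 + eps_deoxy * c2. Multiplied by Delta<L> this is the
# per-beat absorbance swing of each channel.
effective_extinction <- function(state, optics) {
  optics$ext_oxy * state$c1 + optics$ext_deoxy * state$c2
}

#' Closed-form ratio-of-ratios between two wavelength channels
#'
#' The pulsatile absorbance swing at wavelength i is
#' (eps_oxy_i c1 + eps_deoxy_i c2) * Delta<L>; taking the ratio between two
#' channels cancels the path-length term Delta<L> (and the incident
#' intensity), leaving a quantity that depends only on the extinction
#' spectra and the two hemoglobin concentrations. This is the quantity the
#' AC/DC ratio features estimate from measured signals.
#'
#' @param i,j channel indices in 1..8, i != j.
#' @param state a [physio_state()].
#' @param optics an [optical_config()].
#'
#' @return The dimensionless theoretical ratio R_ij.
#' @export
theoretical_ratio <- function(i, j, state, optics = optical_config()) {
  stopifnot(inherits(state, "physio_state"), inherits(optics, "optical_config"))
  n <- length(optics$wavelengths)
  if (!(i %in% seq_len(n)) || !(j %in% seq_len(n)))
    stop("channel indices must be in 1..", n)
  if (i == j) stop("invalid pair: i and j must differ")
  eff <- effective_extinction(state, optics)
  eff[i] / eff[j]
}

#' All 56 theoretical ratios in the fixed feature order
#'
#' @inheritParams theoretical_ratio
#' @return Named numeric vector of length 56, ordered (R_12, ..., R_18,
#'   R_21, R_23, ..., R_87).
#' @export
theoretical_ratios <- function(state, optics = optical_config()) {
  eff <- effective_extinction(state, optics)
  idx <- ratio_pair_index(length(eff))
  out <- eff[idx$i] / eff[idx$j]
  names(out) <- ratio_names(optics$wavelengths)
  out
}
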