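# Hemodynamic response model and generator parameters.

#' Parameters of the synthetic hemodynamic world
#'
#' Bundles every knob of the synthetic fNIRS generator with defaults
#' chosen to emulate bilateral hand-movement recordings: a canonical
#' double-gamma oxy-hemoglobin response peaking `peak_delay` seconds
#' after the cue, an inverted and lagged deoxy-hemoglobin counterpart,
#' weaker responses for motor imagery than for motor execution
#' (`mi_gain`), a weak ipsilateral echo of the contralateral activation,
#' white measurement noise, slow physiological oscillations (Mayer
#' waves, respiration, cardiac pulsation) and per-channel linear drift.
#'
#' The evoked per-block response mixes a dominant phasic component (an
#' amplitude-scaled double-gamma time-locked to cue onset, modelling the
#' strong initial engagement and rapid adaptation of repetitive
#' clenching) with a smaller sustained component (a block-long boxcar
#' convolved with the same kernel, weight `sustain`).  The mix makes the
#' classifier output peak just after `peak_delay` seconds from the cue
#' and then decay to a positive plateau for the rest of the block, so
#' task seconds stay discriminable throughout -- the regime in which
#' per-second motor-execution decoding reaches roughly 80 percent.
#'
#' @param peak_delay s to the positive HRF peak (default 5).
#' @param undershoot_delay s to the (optional) post-stimulus undershoot.
#' @param undershoot_ratio undershoot depth as a fraction of the peak;
#'   0 disables the undershoot (the default: HbO undershoots are weak
#'   and inconsistent in adult motor fNIRS).
#' @param hbo_amp evoked HbO peak amplitude, micromolar, for motor
#'   execution in fully active contralateral channels.
#' @param mi_gain multiplicative attenuation of motor-imagery responses
#'   relative to execution, in (0, 1].
#' @param hbr_ratio HbR response amplitude as a positive fraction of the
#'   HbO amplitude (the HbR response itself is inverted).
#' @param hbr_lag s by which the HbR dip trails the HbO rise.
#' @param contra_gain,ipsi_gain response gain in the hemisphere
#'   contralateral / ipsilateral to the moving hand; `ipsi_gain` must be
#'   strictly smaller.
#' @param noise_sd white measurement noise, micromolar per sample.
#' @param mayer_amp,mayer_freq,cardiac_amp,cardiac_freq,resp_amp,resp_freq
#'   amplitudes (micromolar) and frequencies (Hz) of the physiological
#'   oscillations.
#' @param drift_slope maximal magnitude of the per-channel linear drift,
#'   micromolar per second (each channel draws a slope uniformly in
#'   `[-drift_slope, drift_slope]`).
#' @param fs sampling rate in Hz (default 7.69).
#' @param active_channel_fraction fraction of each hemisphere's channels
#'   that carry the task response ("motor area").
#' @param sustain fraction of the evoked response contributed by a
#'   sustained (boxcar-convolved) drive, in [0, 1].
#' @return A validated list of class `hemo_params`.
#' @export
hemo_params <- function(peak_delay = 5,
                        undershoot_delay = 15,
                        undershoot_ratio = 0,
                        hbo_amp = 1.0,
                        mi_gain = 0.6,
                        hbr_ratio = 0.3,
                        hbr_lag = 1,
                        contra_gain = 1.0,
                        ipsi_gain = 0.3,
                        noise_sd = 0.45,
                        mayer_amp = 0.10, mayer_freq = 0.10,
                        cardiac_amp = 0.05, cardiac_freq = 1.0,
                        resp_amp = 0.05, resp_freq = 0.30,
                        drift_slope = 0.002,
                        fs = 7.69,
                        active_channel_fraction = 0.25,
                        sustain = 0.2) {
  p <- list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
            undershoot_ratio = undershoot_ratio, hbo_amp = hbo_amp,
            mi_gain = mi_gain, hbr_ratio = hbr_ratio, hbr_lag = hbr_lag,
            contra_gain = contra_gain, ipsi_gain = ipsi_gain,
            noise_sd = noise_sd,
            mayer_amp = mayer_amp, mayer_freq = mayer_freq,
            cardiac_amp = cardiac_amp, cardiac_freq = cardiac_freq,
            resp_amp = resp_amp, resp_freq = resp_freq,
            drift_slope = drift_slope, fs = fs,
            active_channel_fraction = active_channel_fraction,
            sustain = sustain)
  for (nm in names(p)) {
    if (!is_number(p[[nm]])) stop_invalid("`", nm, "` must be a finite number")
  }
  if (p$fs <= 0) stop_invalid("`fs` must be positive")
  if (p$peak_delay <= 0) stop_invalid("`peak_delay` must be positive")
  if (p$undershoot_delay <= 0) stop_invalid("`undershoot_delay` must be positive")
  if (p$undershoot_ratio < 0) stop_invalid("`undershoot_ratio` must be >= 0")
  if (p$mi_gain <= 0 || p$mi_gain > 1) stop_invalid("`mi_gain` must be in (0, 1]")
  if (p$ipsi_gain < 0 || p$ipsi_gain >= p$contra_gain) {
    stop_invalid("`ipsi_gain` must be in [0, contra_gain)")
  }
  if (p$noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  if (p$active_channel_fraction <= 0 || p$active_channel_fraction > 1) {
    stop_invalid("`active_channel_fraction` must be in (0, 1]")
  }
  if (p$sustain < 0 || p$sustain > 1) stop_invalid("`sustain` must be in [0, 1]")
  structure(p, class = "hemo_params")
}

#' Canonical double-gamma hemodynamic response
#'
#' Unit-peak impulse response: a gamma density peaking at
#' `params$peak_delay` minus an optional second gamma (the undershoot)
#' peaking at `params$undershoot_delay`, scaled by
#' `params$undershoot_ratio`.  Both gamma components use unit rate, so
#' the shape parameter is `delay + 1`.  The kernel is causal
#' (`h(t) = 0` for `t < 0`) and decays to zero for large `t`.
#'
#' @param t time in seconds (vectorized).
#' @param params a `hemo_params` object (only the HRF fields are used).
#' @return numeric vector of response amplitudes, peak value 1.
#' @examples
#' canonical_hrf(0, hemo_params())        # 0
#' canonical_hrf(5, hemo_params())        # 1 (peak)
#' @export
canonical_hrf <- function(t, params = hemo_params()) {
  pd <- params$peak_delay
  ud <- params$undershoot_delay
  ratio <- params$undershoot_ratio
  if (pd <= 0 || ud <= 0) stop_invalid("HRF delays must be positive")
  h <- numeric(length(t))
  pos <- which(t >= 0)
  if (length(pos)) {
    tp <- t[pos]
    # unit-peak gamma: density divided by its value at the mode
    g1 <- stats::dgamma(tp, shape = pd + 1, rate = 1) /
      stats::dgamma(pd, shape = pd + 1, rate = 1)
    h[pos] <- g1
    if (ratio > 0) {
      g2 <- stats::dgamma(tp, shape = ud + 1, rate = 1) /
        stats::dgamma(ud, shape = ud + 1, rate = 1)
      h[pos] <- g1 - ratio * g2
    }
  }
  h
}

# Evoked response of one task block sampled on `t` (seconds relative to
# cue onset): a `1 - sustain` phasic part (the HRF itself) plus a
# `sustain` part from a block-long boxcar drive convolved with the HRF,
# the latter normalized to unit peak so `sustain` mixes like-for-like.
block_response <- function(t, block_dur, params) {
  phasic <- canonical_hrf(t, params)
  if (params$sustain <= 0) return(phasic)
  dt <- 1 / params$fs
  tt <- seq(0, block_dur + 6 * params$peak_delay, by = dt)
  kern <- canonical_hrf(tt, params)
  box <- as.numeric(tt < block_dur)
  sust_full <- stats::convolve(box, rev(kern), type = "open")[seq_along(tt)] * dt
  sust_full <- sust_full / max(sust_full)
  sust <- stats::approx(tt, sust_full, xout = pmax(t, 0), yleft = 0,
                        yright = 0)$y
  sust[t < 0] <- 0
  (1 - params$sustain) * phasic + params$sustain * sust
}
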