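#' Configuration for the synthetic ECG/EEG dataset generator
#'
#' Bundles every knob of the generative model: study geometry (subjects,
#' stimuli, window length, sampling rate), the RR-interval modulation model
#' (mean RR plus sinusoidal LF/HF components plus Gaussian jitter), the EEG
#' oscillator model (per-band amplitudes, pink-noise floor, inter-channel
#' phase coupling), the planted label effects, and the artifact injection
#' rate. Defaults describe a resting adult viewing a ~90 s stimulus at
#' 256 Hz, the geometry the downstream analysis assumes.
#'
#' @param n_subjects number of subjects.
#' @param stimuli_per_subject stimuli (windows) per subject; the four
#'   default stimuli cover the four arousal x valence quadrants.
#' @param window_s stimulus window length, seconds.
#' @param fs sampling rate, Hz (ECG and EEG).
#' @param rr_mean_ms mean RR interval, ms.
#' @param lf_amp_ms,hf_amp_ms depths (ms) of the sinusoidal RR modulations
#'   at 0.1 Hz (LF) and 0.25 Hz (HF).
#' @param rr_jitter_ms sd of white Gaussian beat-to-beat jitter, ms.
#' @param arousal_effect multiplier applied to the LF/HF balance (LF up,
#'   HF down) and to EEG beta-band amplitude for high-arousal windows.
#'   1 means no planted effect.
#' @param valence_effect multiplier on the inter-channel phase-coupling
#'   weight for positive-valence windows. 1 means no planted effect.
#' @param coupling_kappa baseline phase-coupling weight in [0, 1]: the
#'   fraction of each channel's band oscillation drawn from a shared
#'   oscillator rather than a channel-private one.
#' @param artifact_rate fraction of 1 s epochs corrupted by
#'   [inject_artifacts()] in generated EEG.
#' @param eeg_noise_sd sd (uV) of the pink-noise floor added per channel.
#' @param band_amps named amplitudes (uV) of the theta/alpha/beta/gamma
#'   oscillators.
#' @param ecg_noise_sd sd (uV) of white noise added to the ECG waveform.
#' @param ecg_wander_uv amplitude (uV) of 0.2 Hz baseline wander in the ECG.
#' @param ambiguity_rate fraction of self-assessment scores drawn at the
#'   bipolarization boundary (score 0 or +1 regardless of quadrant), to
#'   emulate ambivalent ratings.
#' @param seed integer seed; identical configs generate byte-identical
#'   datasets.
#' @return an object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_subjects = 8L,
                             stimuli_per_subject = 4L,
                             window_s = 90,
                             fs = 256,
                             rr_mean_ms = 800,
                             lf_amp_ms = 30,
                             hf_amp_ms = 30,
                             rr_jitter_ms = 10,
                             arousal_effect = 1,
                             valence_effect = 1,
                             coupling_kappa = 0.3,
                             artifact_rate = 0,
                             eeg_noise_sd = 5,
                             band_amps = c(theta = 10, alpha = 20,
                                           beta = 10, gamma = 5),
                             ecg_noise_sd = 20,
                             ecg_wander_uv = 40,
                             ambiguity_rate = 0,
                             seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    stimuli_per_subject = as.integer(stimuli_per_subject),
    window_s = window_s, fs = fs,
    rr_mean_ms = rr_mean_ms, lf_amp_ms = lf_amp_ms, hf_amp_ms = hf_amp_ms,
    rr_jitter_ms = rr_jitter_ms,
    arousal_effect = arousal_effect, valence_effect = valence_effect,
    coupling_kappa = coupling_kappa, artifact_rate = artifact_rate,
    eeg_noise_sd = eeg_noise_sd, band_amps = band_amps,
    ecg_noise_sd = ecg_noise_sd, ecg_wander_uv = ecg_wander_uv,
    ambiguity_rate = ambiguity_rate,
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  amps <- c(cfg$lf_amp_ms, cfg$hf_amp_ms, cfg$rr_jitter_ms,
            cfg$eeg_noise_sd, cfg$band_amps, cfg$ecg_noise_sd)
  if (any(amps < 0)) {
    reject("all amplitudes must be >= 0", "affectpipe_bad_config")
  }
  if (cfg$coupling_kappa < 0 || cfg$coupling_kappa > 1) {
    reject("coupling_kappa must lie in [0, 1]", "affectpipe_bad_config")
  }
  if (cfg$artifact_rate < 0 || cfg$artifact_rate > 1) {
    reject("artifact_rate must lie in [0, 1]", "affectpipe_bad_config")
  }
  if (cfg$window_s <= 0 || cfg$rr_mean_ms <= 0) {
    reject("degenerate config: window_s and rr_mean_ms must be positive",
           "affectpipe_bad_config")
  }
  # highest synthesized frequency is the top of the gamma band (40 Hz)
  if (cfg$fs <= 2 * 40) {
    reject("fs must exceed twice the highest synthesized frequency (40 Hz)",
           "affectpipe_bad_config")
  }
  invisible(cfg)
}

#' Canonical 10-20 channel labels used throughout the package
#' @export
EEG_CHANNELS <- c("Fz", "F3", "F4", "Cz", "C3", "C4", "POz", "P3", "P4")

#' EEG analysis bands (Hz)
#'
#' theta 4-8, alpha 8-12, beta 13-25, gamma 25-40. The delta band is
#' deliberately absent (it indexes deep sleep, not affect).
#' @export
EEG_BANDS <- list(theta = c(4, 8), alpha = c(8, 12),
                  beta = c(13, 25), gamma = c(25, 40))
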