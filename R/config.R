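#' Analysis configuration
#'
#' Collects every tunable analysis constant in one validated list. Defaults
#' follow the operating characteristics stated with the methods they govern:
#' the modulation tests run at level 0.05, a detectability index of at least
#' 3 marks a significant correlogram feature, and pair screening controls
#' the false discovery rate at 0.05.
#'
#' @param cth_bins_per_phase CTH bins allotted to each respiratory phase.
#' @param alpha_cth level of the two respiratory-modulation tests.
#' @param cth_n_shuffles Monte Carlo shuffles for the randomization test.
#' @param corr_bin_width correlogram bin width (s).
#' @param corr_window correlogram half-window (s); lags span +/- this.
#' @param corr_background running-median background width (s) removed
#'   from correlograms before feature detection; slow respiratory
#'   co-modulation spans the whole correlogram window while synaptic
#'   features span a few milliseconds, so departures are measured from
#'   this local background.
#' @param n_surrogates surrogate spike-train pairs per correlogram.
#' @param di_threshold detectability-index cutoff (significant if `>=`).
#' @param fdr_q Benjamini-Hochberg false-discovery-rate level across pairs.
#' @param smooth_width phrenic smoothing window before threshold
#'   crossing (s).
#' @param k_on,k_off hysteresis fractions of the control peak-baseline
#'   span for inspiratory on/off threshold crossings (`k_off < k_on`).
#' @param z_augment per-cycle amplitude/frequency z-score above control
#'   marking augmentation.
#' @param n_consec consecutive augmented cycles required for an
#'   augmentation epoch.
#' @param a_apneusis multiple of control median inspiratory duration
#'   marking apneusis.
#' @param s_sigh multiple of control median peak marking an augmented
#'   burst (sigh).
#' @param t_apnea_floor minimum apnea gap (s); the working threshold is
#'   `max(2 * control median cycle length, t_apnea_floor)`.
#' @param f_gasp maximum time-to-peak as a fraction of burst duration for
#'   a decrementing (gasp-shaped) burst.
#' @param bp_step_height minimum sustained blood-pressure rise (mmHg).
#' @param bp_step_window time (s) within which the rise must be achieved.
#' @param q_sync firing-rate multiple of the session median marking
#'   gasp-synchronous firing.
#' @param sync_halfwidth half-width (s) of the window around gasp onsets.
#' @param sta_window spike-triggered-average half-window (s).
#' @param eps_phasic_frac,eps_phasic_floor the "essentially zero" rate for
#'   phasic labelling: `max(eps_phasic_frac * peak, eps_phasic_floor)`.
#' @param rng_seed integer seed for all stochastic stages.
#' @return a named list of class `gaspnet_config`.
#' @export
analysisConfig <- function(cth_bins_per_phase = 25L,
                           alpha_cth = 0.05,
                           cth_n_shuffles = 1000L,
                           corr_bin_width = 0.0005,
                           corr_window = 0.05,
                           corr_background = 0.025,
                           n_surrogates = 1000L,
                           di_threshold = 3.0,
                           fdr_q = 0.05,
                           smooth_width = 0.05,
                           k_on = 0.2,
                           k_off = 0.1,
                           z_augment = 2,
                           n_consec = 3L,
                           a_apneusis = 2,
                           s_sigh = 1.5,
                           t_apnea_floor = 5,
                           f_gasp = 0.25,
                           bp_step_height = 5,
                           bp_step_window = 2,
                           q_sync = 3,
                           sync_halfwidth = 0.5,
                           sta_window = 0.1,
                           eps_phasic_frac = 0.05,
                           eps_phasic_floor = 0.5,
                           rng_seed = 1L) {
  cfg <- list(cth_bins_per_phase = as.integer(cth_bins_per_phase),
              alpha_cth = alpha_cth, cth_n_shuffles = as.integer(cth_n_shuffles),
              corr_bin_width = corr_bin_width, corr_window = corr_window,
              corr_background = corr_background,
              n_surrogates = as.integer(n_surrogates),
              di_threshold = di_threshold, fdr_q = fdr_q,
              smooth_width = smooth_width, k_on = k_on, k_off = k_off,
              z_augment = z_augment, n_consec = as.integer(n_consec),
              a_apneusis = a_apneusis, s_sigh = s_sigh,
              t_apnea_floor = t_apnea_floor, f_gasp = f_gasp,
              bp_step_height = bp_step_height,
              bp_step_window = bp_step_window,
              q_sync = q_sync, sync_halfwidth = sync_halfwidth,
              sta_window = sta_window,
              eps_phasic_frac = eps_phasic_frac,
              eps_phasic_floor = eps_phasic_floor,
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$cth_bins_per_phase >= 1L, cfg$cth_n_shuffles >= 1L,
            cfg$n_surrogates >= 1L, cfg$n_consec >= 1L,
            cfg$alpha_cth > 0, cfg$alpha_cth < 1,
            cfg$fdr_q > 0, cfg$fdr_q < 1,
            cfg$corr_bin_width > 0, cfg$corr_window > 0,
            cfg$smooth_width > 0, cfg$k_off < cfg$k_on)
  class(cfg) <- "gaspnet_config"
  cfg
}

asConfig <- function(config) {
  if (is.null(config)) return(analysisConfig())
  if (inherits(config, "gaspnet_config")) return(config)
  do.call(analysisConfig, config)
}
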