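#' Loudness model container
#'
#' Bundles the periphery (outer/middle-ear filter + DRNL filterbank), the
#' calibrated auditory-nerve population, the loudness calibration and the
#' healthy-control gain into one object. Two presets are shipped: `"full"`
#' (500 channels, 10-s stimuli, spiking mode — the reproduction profile) and
#' `"desk"` (64 channels, 1-s stimuli, rate mode — the fast profile used by
#' the test suite; contour searches are deterministic there).
#'
#' @param preset `"desk"` or `"full"`.
#' @param n_channels,cf_min,cf_max,sample_rate Filterbank layout overrides.
#' @param duration Stimulus duration (s) for grid evaluations.
#' @param mode Default evaluation mode, `"rate"` or `"spiking"`.
#' @param seed Base seed for all stochastic steps.
#' @param params DRNL parameter list (default: packaged human set).
#' @return An (uncalibrated) `loudness_model`; run [calibrate_model()].
#' @export
build_model <- function(preset = c("desk", "full"), n_channels = NULL,
                        cf_min = 40, cf_max = 13000, sample_rate = 44100,
                        duration = NULL, mode = NULL, seed = 1L,
                        params = NULL) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    desk = list(n_channels = 64L, duration = 1, mode = "rate",
                cal_duration = 4, spont_duration = 6),
    full = list(n_channels = 500L, duration = 10, mode = "spiking",
                cal_duration = 10, spont_duration = 10))
  n_channels <- n_channels %||% defaults$n_channels
  duration <- duration %||% defaults$duration
  mode <- mode %||% defaults$mode
  bank <- make_human_filterbank(n_channels, cf_min, cf_max, sample_rate,
                                params = params, warn_extrapolation = FALSE)
  structure(list(preset = preset, bank = bank,
                 ome = outer_middle_ear_config(),
                 duration = duration, mode = mode,
                 cal_duration = defaults$cal_duration,
                 spont_duration = defaults$spont_duration,
                 seed = as.integer(seed),
                 g_hc = 1, fibers = NULL, spont = NULL, x = NULL,
                 loudness = NULL, calibrated = FALSE),
            class = "loudness_model")
}

#' @export
print.loudness_model <- function(x, ...) {
  cat(sprintf("<loudness_model> preset '%s': %d channels, %g s stimuli, %s mode%s\n",
              x$preset, x$bank$n_channels, x$duration, x$mode,
              if (x$calibrated) sprintf(", calibrated (x = %.3f)", x$x)
              else " (uncalibrated)"))
  invisible(x)
}

#' Calibrate a loudness model
#'
#' Performs the full tuning sequence: (1) calibrate the three LIF fiber
#' classes (drive scaling, thresholds, noise levels, rate transfer tables,
#' saturation rates); (2) measure the per-fiber spontaneous baseline with
#' the 1-kHz, -10 dB SPL probe; (3) fit the loudness exponent `x` against
#' the 1-kHz sone law over 30-90 dB SPL; (4) store the 1-kHz, 40-dB SPL
#' reference response for the sone formula.
#'
#' @param model A [build_model()] object.
#' @param fit_x Fit the loudness exponent (default TRUE; set FALSE to keep
#'   a supplied `x`).
#' @param x Exponent to use when `fit_x = FALSE` (default 1.61).
#' @return The calibrated model.
#' @export
calibrate_model <- function(model, fit_x = TRUE, x = 1.61) {
  model$fibers <- calibrate_fiber_classes(model$bank, seed = model$seed,
                                          ome = model$ome)
  model$calibrated <- TRUE
  model$spont <- measure_spontaneous(model, seed = model$seed + 101L,
                                     duration = model$spont_duration,
                                     mode = "spiking")
  if (fit_x) {
    xc <- calibrate_x_model(model)
    model$x <- xc$x
    model$x_fit <- xc
  } else {
    model$x <- x
  }
  model$loudness <- make_loudness_calibration(model)
  model
}

#' Fit the loudness exponent from model simulations
#'
#' Simulates 1-kHz tones at the given levels (spiking mode, seeded),
#' computes the baseline-subtracted summed AN activity and fits the
#' exponent against the 1-kHz sone law (see [calibrate_x()]).
#'
#' @param model A model with calibrated fibers.
#' @param levels Tone levels in dB SPL (default 30-90 in 10-dB steps).
#' @param duration Simulation length per level (default: the model's
#'   calibration duration).
#' @param seed Base seed.
#' @return List with the fitted `x`, the `levels` and the `evoked` sums.
#' @export
calibrate_x_model <- function(model, levels = seq(30, 90, by = 10),
                              duration = model$cal_duration,
                              seed = model$seed + 211L) {
  stopifnot(model$calibrated)
  spont_sum <- sum(model$spont$rates)
  evoked <- vapply(levels, function(L) {
    st <- synthesize_tone(1000, L, duration,
                          sample_rate = model$bank$sample_rate)
    sum(periphery_rates(st, model$bank, model$fibers, model$ome,
                        seed = seed_for(seed, 1000, L),
                        mode = "spiking")) - spont_sum
  }, 0)
  list(x = calibrate_x(levels, evoked), levels = levels, evoked = evoked)
}

#' Build the loudness calibration from the reference response
#'
#' Runs the 1-kHz, 40-dB SPL reference tone (spiking, seeded) and stores
#' the baseline-subtracted summed response, in the model's current gain
#' context, as the sone-formula denominator. Evaluating
#' [loudness_sones()] on the stored reference responses returns exactly
#' 1 sone by construction.
#'
#' @param model A calibrated model.
#' @param seed Seed for the reference simulation.
#' @param duration Simulation length (default: calibration duration).
#' @return A [loudness_calibration()] with the reference `an_response`
#'   attached as attribute `"reference_response"`.
#' @export
make_loudness_calibration <- function(model, seed = model$seed + 307L,
                                      duration = model$cal_duration) {
  stopifnot(model$calibrated)
  resp <- model_tone_response(model, 1000, 40, duration = duration,
                              seed = seed, mode = "spiking")
  cal <- loudness_calibration(model$x,
                              reference_sum = sum(resp$rates) -
                                sum(resp$spont),
                              spont_sum = sum(resp$spont))
  attr(cal, "reference_response") <- resp
  cal
}

#' Full pipeline response to a pure tone
#'
#' Periphery + AN population + healthy gain, returning the gained
#' `an_response` (spontaneous baseline transformed consistently).
#'
#' @param model A calibrated model.
#' @param frequency,level Tone parameters (Hz, dB SPL).
#' @param duration Stimulus duration (default: model duration).
#' @param seed Seed (default: derived from the model seed and the tone).
#' @param mode `"rate"` or `"spiking"` (default: model mode).
#' @param g_hc Healthy gain override (default: the model's).
#' @return An `an_response`.
#' @export
model_tone_response <- function(model, frequency, level,
                                duration = model$duration, seed = NULL,
                                mode = model$mode, g_hc = model$g_hc) {
  stopifnot(model$calibrated)
  if (is.null(seed)) seed <- seed_for(model$seed, frequency, level)
  st <- synthesize_tone(frequency, level, duration,
                        sample_rate = model$bank$sample_rate)
  rates <- periphery_rates(st, model$bank, model$fibers, model$ome,
                           seed = seed, mode = mode)
  spont <- grid_spont(model, mode)
  resp <- new_an_response(rates, spont, model$bank$cf, mode, duration,
                          frequency = frequency, level = level)
  apply_healthy_gain(resp, g_hc)
}

#' Total summed gain-stage output for a tone
#'
#' Convenience wrapper used for brute-force contour checks: evaluates the
#' full pipeline (optionally with a hyperacusis gain) and returns the total
#' summed activity in sp/s.
#'
#' @inheritParams model_tone_response
#' @param spec Optional [hyperacusis_gain_spec()].
#' @return Summed activity (sp/s).
#' @export
model_summed_activity <- function(model, frequency, level,
                                  duration = model$duration, seed = NULL,
                                  mode = model$mode, g_hc = model$g_hc,
                                  spec = NULL) {
  stopifnot(model$calibrated)
  if (is.null(seed)) seed <- seed_for(model$seed, frequency, level)
  st <- synthesize_tone(frequency, level, duration,
                        sample_rate = model$bank$sample_rate)
  rates <- periphery_rates(st, model$bank, model$fibers, model$ome,
                           seed = seed, mode = mode)
  spont <- grid_spont(model, mode)
  ghc_cf <- eval_gain(g_hc, model$bank$cf)
  out <- apply_gain_stage_matrices(rates, spont, model$bank$cf, ghc_cf,
                                   spec, model$fibers$r_max)
  sum(out$rates)
}
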