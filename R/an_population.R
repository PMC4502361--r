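#' Auditory-nerve population model
#'
#' Each cochlear channel drives three leaky-integrate-and-fire (LIF) fibers
#' representing the three spontaneous-rate (SR) classes of auditory-nerve
#' fibers: low-threshold fibers with a high SR (35 sp/s), medium-threshold
#' fibers (8 sp/s), and high-threshold fibers with a low SR (2 sp/s). The
#' LIF input current is the half-wave rectified basilar-membrane velocity of
#' the channel, scaled by a global drive constant, plus a class-specific
#' white-noise current that produces the spontaneous firing.
#'
#' Two evaluation modes are available: `"spiking"` simulates the LIF
#' population (stochastic, seeded), `"rate"` maps the deterministic mean
#' rectified drive of each channel through per-class rate transfer tables
#' that are measured from the spiking model during calibration. Rate mode is
#' deterministic and monotone in level, which keeps contour searches
#' well-posed and fast.
#'
#' @name an_population
NULL

AN_CLASS_NAMES <- c("low-threshold", "medium-threshold", "high-threshold")
AN_TARGET_SR <- c(35, 8, 2)

#' Fiber class parameter table
#'
#' @param theta Activation thresholds (model units), one per class,
#'   increasing from the low-threshold to the high-threshold class.
#' @param sigma Noise-current levels (model units), one per class.
#' @param target_sr Target spontaneous rates in sp/s (default 35, 8, 2).
#' @return Data frame with one row per class.
#' @export
fiber_class_params <- function(theta, sigma, target_sr = AN_TARGET_SR) {
  stopifnot(length(theta) == 3, length(sigma) == 3,
            all(diff(theta) > 0), all(diff(target_sr) < 0))
  data.frame(name = AN_CLASS_NAMES, target_sr = target_sr,
             activation_threshold = theta, noise_current_level = sigma)
}

# Spike rate of one LIF fiber for a deterministic current trace (sp/s).
lif_rate <- function(current, theta, sigma, tau, t_ref, dt) {
  n <- length(current)
  cpp_lif_spike_count(current, theta, sigma, tau, t_ref, dt) / (n * dt)
}

# Noise-only spontaneous rate estimate for one class (duration in s).
spont_rate_estimate <- function(theta, sigma, tau, t_ref, dt, duration) {
  lif_rate(numeric(round(duration / dt)), theta, sigma, tau, t_ref, dt)
}

# Solve for the noise level that yields the target spontaneous rate.
# Rate is monotone increasing in sigma; coarse log-grid scan followed by
# secant refinement on log(rate) vs log(sigma).
calibrate_noise_level <- function(target, theta, tau, t_ref, dt,
                                  scan_duration = 15,
                                  refine_duration = NULL) {
  # low-rate classes need proportionally longer estimation windows for the
  # same relative precision (~1500 spikes per evaluation)
  if (is.null(refine_duration)) refine_duration <- max(60, 1500 / target)
  sigmas <- theta * 10^seq(-1.1, 0.3, length.out = 12)
  rates <- vapply(sigmas, function(s)
    spont_rate_estimate(theta, s, tau, t_ref, dt, scan_duration), 0)
  rates <- pmax(cummax(rates), 1e-3)
  sigma <- exp(stats::approx(log(rates), log(sigmas), xout = log(target),
                             rule = 2, ties = "ordered")$y)
  for (i in 1:3) {
    r <- spont_rate_estimate(theta, sigma, tau, t_ref, dt, refine_duration)
    r2 <- spont_rate_estimate(theta, sigma * 1.15, tau, t_ref, dt,
                              refine_duration)
    slope <- (log(pmax(r2, 1e-3)) - log(pmax(r, 1e-3))) / log(1.15)
    if (!is.finite(slope) || slope < 0.5) slope <- 3
    step <- (log(target) - log(pmax(r, 1e-3))) / slope
    sigma <- sigma * exp(max(-0.5, min(0.5, step)))
  }
  sigma
}

# Rate transfer table for one class: spiking rate as a function of the mean
# rectified drive, measured with a 1-kHz rectified-sinusoid current.
build_rate_table <- function(theta, sigma, tau, t_ref, dt, drive_grid,
                             carrier = 1000, duration = 4, n_rep = 3,
                             target_sr = NULL) {
  tt <- seq(0, duration, by = dt)[-1]
  template <- pmax(0, sin(2 * pi * carrier * tt))
  template <- template / mean(template) # unit-mean drive
  rate <- vapply(drive_grid, function(m) {
    if (m == 0 && !is.null(target_sr)) return(target_sr)
    mean(vapply(seq_len(n_rep), function(i)
      lif_rate(m * template, theta, sigma, tau, t_ref, dt), 0))
  }, 0)
  rate <- cummax(rate) # enforce monotonicity against sampling noise
  list(drive = drive_grid, rate = rate)
}

rate_from_drive <- function(table, m) {
  stats::approx(table$drive, table$rate, xout = pmin(m, max(table$drive)),
                rule = 2, ties = "ordered")$y
}

#' Calibrate the three auditory-nerve fiber classes
#'
#' Fixes the drive scaling and class thresholds from the deterministic
#' drive-level curve of the on-CF channel for 1-kHz tones (deterministic
#' thresholds placed at `threshold_levels_db` dB SPL), then tunes each
#' class's noise-current level so the spontaneous rates hit the targets, and
#' finally measures per-class rate transfer tables and saturation rates from
#' the spiking model.
#'
#' @param bank A [make_human_filterbank()] configuration.
#' @param targets Target spontaneous rates in sp/s (default 35, 8, 2).
#' @param threshold_levels_db Tone levels (dB SPL, 1 kHz) at which the three
#'   deterministic activation thresholds are placed (defaults 10/35/60 dB,
#'   the characteristic threshold spread of high-, medium- and low-SR
#'   auditory-nerve fibers).
#' @param tau Membrane time constant in seconds (default 5 ms).
#' @param t_ref Absolute refractory period in seconds (default 4 ms, giving
#'   a saturation rate near 250 sp/s as in real auditory-nerve fibers).
#' @param ome Outer/middle-ear configuration used for the calibration tones.
#' @param seed Integer seed for the stochastic calibration steps.
#' @return A `fiber_population` object (class parameters, drive scale, rate
#'   tables, per-class saturation rates `r_max`).
#' @export
calibrate_fiber_classes <- function(bank, targets = AN_TARGET_SR,
                                    threshold_levels_db = c(10, 35, 60),
                                    tau = 0.005, t_ref = 0.004,
                                    ome = outer_middle_ear_config(),
                                    seed = 1L) {
  fs <- bank$sample_rate
  dt <- 1 / fs
  j1k <- which.min(abs(bank$cf - 1000))
  # deterministic mean rectified BM drive of the on-CF channel vs level
  drive_at <- function(level) {
    st <- synthesize_tone(1000, level, duration = 0.25, sample_rate = fs)
    bm <- drnl_channel_trace(apply_outer_middle_ear(st, ome), bank, j1k)
    cpp_rectified_mean(bm[-seq_len(round(0.02 * fs))])
  }
  m_thr <- vapply(threshold_levels_db, drive_at, 0)
  if (any(m_thr <= 0) || any(diff(m_thr) <= 0))
    stop("fiber class calibration failed: drive-level curve is not ",
         "positive and increasing at the threshold placement levels")
  drive_scale <- 1 / m_thr[1]
  theta <- m_thr / m_thr[1]
  m_top <- drive_at(110) * drive_scale

  classes <- with_seed(seed, {
    sigma <- vapply(seq_len(3), function(k)
      calibrate_noise_level(targets[k], theta[k], tau, t_ref, dt), 0)
    fiber_class_params(theta, sigma, targets)
  })

  drive_grid <- c(0, 10^seq(log10(0.02), log10(3 * m_top), length.out = 23))
  tables <- with_seed(seed + 1L, lapply(seq_len(3), function(k)
    build_rate_table(classes$activation_threshold[k],
                     classes$noise_current_level[k],
                     tau, t_ref, dt, drive_grid,
                     target_sr = targets[k])))
  names(tables) <- AN_CLASS_NAMES
  r_max <- vapply(tables, function(tb) max(tb$rate), 0)

  structure(list(classes = classes, drive_scale = drive_scale,
                 tau = tau, t_ref = t_ref,
                 threshold_levels_db = threshold_levels_db,
                 rate_tables = tables, r_max = r_max,
                 sample_rate = fs, seed = seed),
            class = "fiber_population")
}

#' @export
print.fiber_population <- function(x, ...) {
  cat("<fiber_population> 3 LIF classes per channel\n")
  print(cbind(x$classes, r_max = unname(x$r_max)))
  invisible(x)
}

new_an_response <- function(rates, spont, cf, mode, duration,
                            frequency = NA_real_, level = NA_real_) {
  rownames(rates) <- AN_CLASS_NAMES
  structure(list(rates = rates, spont = spont, cf = cf, mode = mode,
                 duration = duration,
                 stimulus = c(frequency = frequency, level = level)),
            class = "an_response")
}

#' @export
print.an_response <- function(x, ...) {
  cat(sprintf(
    "<an_response> %d fibers (%d channels x 3 classes), mode '%s'\n",
    length(x$rates), ncol(x$rates), x$mode))
  cat(sprintf("  class means (sp/s): %s\n",
              paste(sprintf("%.1f", rowMeans(x$rates)), collapse = ", ")))
  invisible(x)
}

# Rates of the three fibers on one channel given the channel BM trace.
channel_fiber_rates <- function(bm, fibers, mode, dt) {
  drive <- fibers$drive_scale * pmax(0, bm)
  if (mode == "rate") {
    m <- mean(drive)
    vapply(seq_len(3), function(k)
      rate_from_drive(fibers$rate_tables[[k]], m), 0)
  } else {
    cl <- fibers$classes
    as.numeric(cpp_lif_channel_counts(drive, cl$activation_threshold,
                                      cl$noise_current_level,
                                      fibers$tau, fibers$t_ref, dt)) /
      (length(bm) * dt)
  }
}

#' Auditory-nerve response to per-channel BM velocity
#'
#' @param bm_outputs Matrix of BM velocity from [apply_drnl()]
#'   (samples x channels).
#' @param fibers A calibrated `fiber_population`.
#' @param cf Channel characteristic frequencies (Hz).
#' @param seed Integer seed (spiking mode).
#' @param mode `"spiking"` (stochastic LIF simulation) or `"rate"`
#'   (deterministic transfer-table lookup).
#' @param spont Optional per-fiber spontaneous-rate matrix to attach
#'   (3 x channels); defaults to the class targets.
#' @return An `an_response` object with a 3 x channels rate matrix.
#' @export
an_respond <- function(bm_outputs, fibers, cf, seed = 1L,
                       mode = c("rate", "spiking"), spont = NULL) {
  mode <- match.arg(mode)
  nch <- ncol(bm_outputs)
  dt <- 1 / fibers$sample_rate
  duration <- nrow(bm_outputs) * dt
  if (mode == "spiking" && duration < 0.5)
    warning("stimulus shorter than 0.5 s: spiking rate estimates will be ",
            "noisy", call. = FALSE)
  if (is.null(spont))
    spont <- matrix(fibers$classes$target_sr, nrow = 3, ncol = nch)
  run <- function() {
    rates <- matrix(0, nrow = 3, ncol = nch)
    for (j in seq_len(nch))
      rates[, j] <- channel_fiber_rates(bm_outputs[, j], fibers, mode, dt)
    rates
  }
  rates <- if (mode == "spiking") with_seed(seed, run()) else run()
  new_an_response(rates, spont, cf, mode, duration)
}

# Full periphery + AN evaluation for a stimulus, looping channels so the
# full BM matrix is never materialised (important for the 500-channel
# profile).
periphery_rates <- function(stimulus, bank, fibers, ome, seed = 1L,
                            mode = "rate") {
  x <- apply_outer_middle_ear(stimulus, ome) * bank$stapes_scale
  dt <- 1 / bank$sample_rate
  run <- function() {
    rates <- matrix(0, nrow = 3, ncol = bank$n_channels)
    for (j in seq_len(bank$n_channels)) {
      bm <- cpp_drnl_channel(x, bank$channels[[j]])
      rates[, j] <- channel_fiber_rates(bm, fibers, mode, dt)
    }
    rates
  }
  if (mode == "spiking") with_seed(seed, run()) else run()
}

#' Measure per-fiber spontaneous rates
#'
#' Presents the spontaneous-activity probe (a 1-kHz tone at -10 dB SPL,
#' which leaves the fibers essentially undriven) and returns the resulting
#' response; the per-fiber rates are the model's baseline `R_ANsp`.
#'
#' @param model A calibrated [build_model()] object, or a list with elements
#'   `bank`, `fibers`, `ome`.
#' @param seed Integer seed.
#' @param duration Probe duration in seconds (default 10, as for stable
#'   spontaneous-rate estimates).
#' @param mode `"spiking"` or `"rate"`; rate mode returns the class targets
#'   exactly.
#' @return An `an_response` whose rates are the spontaneous baseline.
#' @export
measure_spontaneous <- function(model, seed = 1L, duration = 10,
                                mode = c("spiking", "rate")) {
  mode <- match.arg(mode)
  st <- synthesize_tone(1000, -10, duration,
                        sample_rate = model$bank$sample_rate)
  rates <- periphery_rates(st, model$bank, model$fibers, model$ome,
                           seed = seed, mode = mode)
  new_an_response(rates, rates, model$bank$cf, mode, duration,
                  frequency = 1000, level = -10)
}
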