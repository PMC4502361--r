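#' Auditory periphery: outer/middle ear and DRNL cochlear filterbank
#'
#' The periphery converts a calibrated pressure waveform into per-channel
#' basilar-membrane (BM) velocity. Sound pressure first passes a parallel
#' three-band Butterworth filter standing in for the outer/middle-ear
#' transfer (output scaled to stapes velocity), then a bank of
#' dual-resonance non-linear (DRNL) filters: each channel sums a linear path
#' (gain, two first-order gammatones, four second-order Butterworth
#' low-passes) and a compressive path (three gammatones, broken-stick
#' non-linearity, three gammatones, three low-passes).
#'
#' @name periphery
NULL

# ---- ERB scale (Glasberg & Moore form) --------------------------------------

#' ERB-number of a frequency
#' @param f Frequency in Hz.
#' @return ERB-number (Cam).
#' @export
erb_number <- function(f) 21.4 * log10(1 + 0.00437 * f)

#' Frequency corresponding to an ERB-number
#' @param e ERB-number (Cam).
#' @return Frequency in Hz.
#' @export
erb_to_hz <- function(e) (10^(e / 21.4) - 1) / 0.00437

#' Frequencies evenly spaced on the ERB scale
#' @param f_min,f_max Range endpoints in Hz (included exactly).
#' @param n Number of frequencies.
#' @return Numeric vector of length `n`, strictly increasing.
#' @export
erb_space <- function(f_min, f_max, n) {
  stopifnot(n >= 2, f_min > 0, f_min < f_max)
  erb_to_hz(seq(erb_number(f_min), erb_number(f_max), length.out = n))
}

# ---- Outer / middle ear -----------------------------------------------------

#' Outer/middle-ear filter configuration
#'
#' Three parallel bandpass branches with Butterworth magnitude responses:
#' 1900-4200 Hz at -2 dB, 4500-6300 Hz at -3 dB, and 8000-12000 Hz at
#' -19 dB. The branches are applied as zero-phase filters so the parallel
#' sum is free of inter-branch phase cancellation; the edge orders are
#' asymmetric (see the parameter file) so each band's printed gain is
#' realised cleanly while the below-band skirt of the lowest branch keeps
#' the shallow roll-off that forms the model's only low-frequency pathway.
#'
#' @param bands Data frame with columns `low_cut`, `high_cut`, `gain_db`,
#'   `order_low`, `order_high`.
#' @return An `ome_config` object.
#' @export
outer_middle_ear_config <- function(bands = NULL) {
  if (is.null(bands)) {
    prm <- default_drnl_params()$outer_middle_ear
    bands <- do.call(rbind, lapply(prm$bands, as.data.frame))
  }
  stopifnot(nrow(bands) == 3L, all(bands$low_cut < bands$high_cut))
  structure(list(bands = bands, filter_family = "butterworth"),
            class = "ome_config")
}

# Butterworth bandpass magnitude with separate edge orders. Uses the
# standard bandpass frequency transform X = (f^2 - f1 f2) / (f (f2 - f1)),
# which is -3 dB exactly at both cut-offs for any order and flat in the
# passband; below the geometric centre the low-edge order applies, above it
# the high-edge order.
butterworth_band_magnitude <- function(f, low_cut, high_cut, order_low,
                                       order_high) {
  fc <- sqrt(low_cut * high_cut)
  X <- (f^2 - low_cut * high_cut) / (pmax(f, 1e-9) * (high_cut - low_cut))
  n <- ifelse(f < fc, order_low, order_high)
  1 / sqrt(1 + X^(2 * n))
}

# Combined magnitude response of the parallel bank at frequencies f (Hz).
ome_magnitude <- function(f, config) {
  out <- 0
  for (i in seq_len(nrow(config$bands))) {
    bd <- config$bands[i, ]
    out <- out + 10^(bd$gain_db / 20) *
      butterworth_band_magnitude(f, bd$low_cut, bd$high_cut,
                                 bd$order_low, bd$order_high)
  }
  out
}

#' Apply the outer/middle-ear filter
#'
#' The output is the sum of the three gain-scaled bandpass branches applied
#' in parallel (zero-phase), a proxy for stapes velocity (before the stapes
#' scaling constant applied by the filterbank). Implemented in the
#' frequency domain: the spectrum is multiplied by the combined magnitude
#' response, which is exact and linear/time-invariant.
#'
#' @param stimulus A `stimulus`, or a numeric waveform (then `sample_rate`
#'   must be given).
#' @param config An [outer_middle_ear_config()].
#' @param sample_rate Sampling rate in Hz when `stimulus` is a bare vector.
#' @return Filtered waveform (numeric vector).
#' @export
apply_outer_middle_ear <- function(stimulus, config = outer_middle_ear_config(),
                                   sample_rate = NULL) {
  if (inherits(stimulus, "stimulus")) {
    x <- stimulus$samples
    fs <- stimulus$sample_rate
  } else {
    x <- stimulus
    fs <- sample_rate
    if (is.null(fs)) stop("sample_rate required for a bare waveform")
  }
  if (fs < 2 * max(config$bands$high_cut))
    stop("sample rate too low to represent the upper cut-off of the ",
         "outer/middle-ear filter (need >= ",
         2 * max(config$bands$high_cut), " Hz)")
  n <- length(x)
  fr <- (seq_len(n) - 1) * fs / n
  fr <- pmin(fr, fs - fr) # two-sided spectrum folded to [0, fs/2]
  Re(stats::fft(stats::fft(x) * ome_magnitude(fr, config),
                inverse = TRUE)) / n
}

# ---- DRNL parameters and filterbank -----------------------------------------

#' Read a DRNL parameter file
#'
#' Parameter files are YAML with per-path log-linear regression coefficients
#' (`log10(param) = p0 + m * log10(cf)`), gammatone/low-pass cascade counts,
#' the linear-gain slope magnitude `g0`, and the stapes scaling constant.
#' [write_drnl_params()] round-trips the structure bit-exactly.
#'
#' @param path YAML file path; default: the packaged human parameter set.
#' @return Nested list of parameters.
#' @export
read_drnl_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "drnl_human_params.yaml",
                        package = "anloud", mustWork = TRUE)
  yaml::read_yaml(path)
}

default_drnl_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_drnl_params()
    cache
  }
})

#' Write a DRNL parameter file
#' @param params Parameter list as returned by [read_drnl_params()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_drnl_params <- function(params, path) {
  yaml::write_yaml(params, path, precision = 15)
  invisible(path)
}

reg10 <- function(reg, cf) 10^(reg$p0 + reg$m * log10(cf))

# Gammatone pole for a first-order stage at frequency f, bandwidth bw.
gt_pole <- function(f, bw, fs) {
  r <- exp(-2 * pi * bw / fs)
  r * exp(1i * 2 * pi * f / fs)
}

# Per-channel coefficients ready for the C++ DRNL kernel.
channel_params <- function(cf, prm, fs) {
  lin <- prm$linear
  nl <- prm$nonlinear
  lg10 <- log10(cf)
  a <- 10^(nl$a$p0 + nl$a$m * lg10)
  b <- 10^(nl$b$p0 + nl$b$m * lg10)
  c <- 10^(nl$c$p0 + nl$c$m * lg10)
  lin_gain <- 10^(lin$gain_p0 - lin$g0 * lg10)
  lp_design <- function(cutoff, order) {
    signal::butter(order, min(cutoff / (fs / 2), 0.98), type = "low")
  }
  lin_lp <- lp_design(reg10(lin$lp_cutoff, cf), lin$lowpass_order)
  nl_lp <- lp_design(reg10(nl$lp_cutoff, cf), nl$lowpass_order)
  p_lin <- gt_pole(reg10(lin$cf, cf), reg10(lin$bw, cf), fs)
  p_nl <- gt_pole(reg10(nl$cf, cf), reg10(nl$bw, cf), fs)
  list(cf = cf, a = a, b = b, c = c,
       lin_gain = lin_gain,
       lin_pole_re = Re(p_lin), lin_pole_im = Im(p_lin),
       lin_n_gt = as.integer(lin$n_gammatone),
       lin_lp_b = as.numeric(lin_lp$b), lin_lp_a = as.numeric(lin_lp$a),
       lin_n_lp = as.integer(lin$n_lowpass),
       nl_pole_re = Re(p_nl), nl_pole_im = Im(p_nl),
       nl_n_gt = as.integer(nl$n_gammatone),
       nl_lp_b = as.numeric(nl_lp$b), nl_lp_a = as.numeric(nl_lp$a),
       nl_n_lp = as.integer(nl$n_lowpass))
}

#' Build the human DRNL filterbank
#'
#' Channel characteristic frequencies (CFs) are spaced evenly on the ERB
#' scale with the endpoints anchored exactly; all per-channel coefficients
#' come from the log-linear regressions of the human parameter set (see
#' [read_drnl_params()]).
#'
#' @param n_channels Number of channels (>= 2); default 500.
#' @param cf_min,cf_max CF range in Hz; defaults 40 and 13000.
#' @param sample_rate Sampling rate the filters are designed for.
#' @param params Parameter list (default: packaged human set).
#' @param warn_extrapolation Warn when the CF range extends beyond the
#'   regressions' stated validity range.
#' @return A `filterbank_config` object.
#' @export
make_human_filterbank <- function(n_channels = 500, cf_min = 40,
                                  cf_max = 13000, sample_rate = 44100,
                                  params = NULL,
                                  warn_extrapolation = TRUE) {
  stopifnot(n_channels >= 2, cf_min > 0, cf_min < cf_max)
  if (is.null(params)) params <- default_drnl_params()
  if (sample_rate < 2 * cf_max)
    stop("sample rate must exceed twice the top characteristic frequency")
  vr <- params$validity_range_hz
  if (warn_extrapolation && (cf_min < vr[1] || cf_max > vr[2]))
    warning(sprintf(paste0("CF range [%g, %g] Hz extends beyond the validity",
                           " range [%g, %g] Hz of the parameter regressions;",
                           " coefficients are extrapolated"),
                    cf_min, cf_max, vr[1], vr[2]), call. = FALSE)
  cfs <- erb_space(cf_min, cf_max, n_channels)
  channels <- lapply(cfs, channel_params, prm = params, fs = sample_rate)
  structure(list(channels = channels, cf = cfs,
                 n_channels = as.integer(n_channels),
                 cf_min = cf_min, cf_max = cf_max,
                 sample_rate = sample_rate,
                 stapes_scale = params$stapes_scale,
                 params = params),
            class = "filterbank_config")
}

#' @export
print.filterbank_config <- function(x, ...) {
  cat(sprintf("<filterbank_config> %d DRNL channels, CF %g-%g Hz @ %g Hz\n",
              x$n_channels, x$cf_min, x$cf_max, x$sample_rate))
  invisible(x)
}

#' Broken-stick non-linearity
#'
#' `y = sign(i) * min(a |i|, b |i|^c)`: linear with slope `a` for small
#' inputs, compressive with exponent `c` above the knee.
#'
#' @param input Numeric input (stapes velocity, m/s).
#' @param a,b Positive coefficients of the linear and compressive branches.
#' @param c Compression exponent in (0, 1).
#' @return Numeric vector of the same length as `input`.
#' @export
broken_stick <- function(input, a, b, c) {
  stopifnot(a > 0, b > 0, c > 0, c < 1)
  cpp_broken_stick(as.numeric(input), a, b, c)
}

#' Run the DRNL filterbank
#'
#' @param waveform Outer/middle-ear filtered waveform (before stapes
#'   scaling; the bank's `stapes_scale` is applied internally).
#' @param bank A [make_human_filterbank()] configuration.
#' @return Matrix of BM velocity (m/s), `length(waveform)` rows x
#'   `n_channels` columns.
#' @export
apply_drnl <- function(waveform, bank) {
  if (length(bank$channels) == 0) stop("filterbank has no channels")
  x <- as.numeric(waveform) * bank$stapes_scale
  out <- matrix(0, nrow = length(x), ncol = bank$n_channels)
  for (j in seq_along(bank$channels))
    out[, j] <- cpp_drnl_channel(x, bank$channels[[j]])
  colnames(out) <- sprintf("cf%.0f", bank$cf)
  out
}

# Single-channel BM trace without materialising the whole bank output.
drnl_channel_trace <- function(waveform, bank, j) {
  cpp_drnl_channel(as.numeric(waveform) * bank$stapes_scale,
                   bank$channels[[j]])
}

#' Compression region of a DRNL channel for on-CF tones
#'
#' Computes, from the channel coefficients and the outer/middle-ear
#' response, the tone level (dB SPL) at which the broken-stick knee is
#' reached (`knee_spl`, onset of compression) and the level at which the
#' linear path output equals the non-linear path output
#' (`crossover_spl`, above which the response returns towards linear and
#' the two paths interfere). Between roughly `knee_spl + 5` and
#' `crossover_spl - 15` dB the input-output slope of the channel equals the
#' compression exponent `c`.
#'
#' @param bank A filterbank configuration.
#' @param channel Channel index.
#' @param config Outer/middle-ear configuration.
#' @return List with `knee_spl`, `crossover_spl` and the channel's `c`.
#' @export
drnl_compression_window <- function(bank, channel,
                                    config = outer_middle_ear_config()) {
  prm <- bank$channels[[channel]]
  i_knee <- (prm$b / prm$a)^(1 / (1 - prm$c))
  i_cross <- (prm$b / prm$lin_gain)^(1 / (1 - prm$c))
  # stapes velocity amplitude per unit dB SPL tone at CF
  amp0 <- sqrt(2) * P_REF * ome_magnitude(prm$cf, config) * bank$stapes_scale
  list(knee_spl = 20 * log10(i_knee / amp0),
       crossover_spl = 20 * log10(i_cross / amp0),
       c = prm$c)
}
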