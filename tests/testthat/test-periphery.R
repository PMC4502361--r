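band_power_gain <- function(x, y, fs, lo, hi) {
  n <- length(x)
  fr <- (seq_len(n) - 1) * fs / n
  sel <- fr >= lo & fr <= hi
  10 * log10(mean(abs(stats::fft(y))[sel]^2 / n) /
             mean(abs(stats::fft(x))[sel]^2 / n))
}

test_that("outer/middle-ear filter realises the printed band gains", {
  ns <- synthesize_white_noise(60, 10, seed = 1)
  y <- apply_outer_middle_ear(ns)
  gains <- c(band_power_gain(ns$samples, y, 44100, 2500, 4000),
             band_power_gain(ns$samples, y, 44100, 4700, 6100),
             band_power_gain(ns$samples, y, 44100, 9000, 11000))
  expect_equal(gains, c(-2, -3, -19), tolerance = 0.5 / 19) # +-0.5 dB
  expect_lt(abs(gains[1] - (-2)), 0.5)
  expect_lt(abs(gains[2] - (-3)), 0.5)
  expect_lt(abs(gains[3] - (-19)), 0.5)
})

test_that("tones far outside all passbands are strongly attenuated", {
  st <- synthesize_tone(200, 60, 0.5)
  y <- apply_outer_middle_ear(st)
  atten <- 20 * log10(sqrt(mean(y^2)) / sqrt(mean(st$samples^2)))
  expect_lt(atten, -30) # far exceeds the deepest branch gain of -19 dB
})

test_that("outer/middle-ear filter is linear and rejects low sample rates", {
  st <- synthesize_tone(3000, 50, 0.2)
  y1 <- apply_outer_middle_ear(st)
  y2 <- apply_outer_middle_ear(st$samples * 3.7, sample_rate = 44100)
  expect_equal(y2, y1 * 3.7, tolerance = 1e-10)
  expect_error(apply_outer_middle_ear(st$samples, sample_rate = 16000),
               "sample rate")
})

test_that("broken-stick non-linearity follows its printed formula", {
  expect_identical(broken_stick(0, a = 100, b = 0.1, c = 0.25), 0)
  i <- seq(-1e-3, 1e-3, length.out = 101)
  y <- broken_stick(i, a = 1000, b = 0.2, c = 0.25)
  expect_equal(y, -rev(y), tolerance = 1e-12) # odd symmetry
  # linear branch where a|i| < b|i|^c
  small <- c(1e-9, 5e-9, 1e-8)
  expect_equal(broken_stick(small, a = 1000, b = 0.2, c = 0.25),
               1000 * small, tolerance = 1e-12)
  # brute-force oracle: pointwise formula
  set.seed(1)
  ii <- stats::rnorm(200, sd = 1e-3)
  expect_equal(broken_stick(ii, a = 500, b = 0.15, c = 0.3),
               sign(ii) * pmin(500 * abs(ii), 0.15 * abs(ii)^0.3),
               tolerance = 1e-12)
  expect_error(broken_stick(1, a = -1, b = 1, c = 0.5))
  expect_error(broken_stick(1, a = 1, b = 1, c = 1.2))
})

test_that("compressive-branch slope equals c on a log-log grid", {
  a <- 2000; b <- 0.1; c <- 0.25
  knee <- (b / a)^(1 / (1 - c))
  ii <- knee * 10^seq(1, 3, length.out = 40) # well above the knee
  y <- broken_stick(ii, a, b, c)
  slopes <- diff(log10(y)) / diff(log10(ii))
  expect_true(all(abs(slopes - c) < 0.05))
})

test_that("human filterbank CFs are ERB-spaced with anchored endpoints", {
  bank <- test_bank()
  expect_identical(bank$n_channels, 32L)
  expect_equal(bank$cf[1], 40)
  expect_equal(bank$cf[32], 13000)
  expect_true(all(diff(bank$cf) > 0))
  steps <- diff(erb_number(bank$cf))
  expect_lt(max(abs(steps - steps[1])) / steps[1], 1e-6)
  two <- make_human_filterbank(2, 40, 13000, warn_extrapolation = FALSE)
  expect_equal(two$cf, c(40, 13000))
  expect_warning(make_human_filterbank(8, 40, 13000), "validity")
})

test_that("per-channel DRNL coefficients follow the parameter regressions", {
  bank <- test_bank()
  prm <- read_drnl_params()
  j <- 20
  cf <- bank$cf[j]
  ch <- bank$channels[[j]]
  expect_equal(ch$a, 10^(prm$nonlinear$a$p0 + prm$nonlinear$a$m * log10(cf)))
  expect_equal(ch$b, 10^(prm$nonlinear$b$p0 + prm$nonlinear$b$m * log10(cf)))
  expect_equal(ch$c, 0.25, tolerance = 1e-6)
  expect_equal(ch$lin_gain,
               10^(prm$linear$gain_p0 - prm$linear$g0 * log10(cf)))
  expect_gt(ch$a, 0)
  expect_gt(ch$b, 0)
  expect_identical(ch$nl_n_gt, 3L) # three gammatones in the compressive path
  expect_identical(ch$lin_n_gt, 2L)
})

test_that("DRNL parameter files round-trip bit-exactly", {
  prm <- read_drnl_params()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_drnl_params(prm, path)
  expect_identical(read_drnl_params(path), prm)
})

test_that("DRNL level dependence: linear at low level, slope c mid-level", {
  bank <- test_bank()
  j <- which.min(abs(bank$cf - 1000))
  win <- drnl_compression_window(bank, j)
  f <- bank$cf[j]
  io <- function(levels) {
    vapply(levels, function(L) {
      st <- synthesize_tone(f, L, 0.25)
      bm <- anloud:::drnl_channel_trace(apply_outer_middle_ear(st), bank, j)
      sqrt(mean(bm[-seq_len(2000)]^2))
    }, 0)
  }
  low <- seq(win$knee_spl - 30, win$knee_spl - 15, by = 5)
  slopes_low <- diff(20 * log10(io(low))) / diff(low)
  expect_true(all(abs(slopes_low - 1) < 0.05))
  comp <- seq(win$knee_spl + 5, win$crossover_spl - 15, length.out = 5)
  fit <- stats::lm(y ~ x, data = data.frame(x = comp, y = 20 * log10(io(comp))))
  expect_lt(abs(unname(stats::coef(fit)[2]) - win$c), 0.05)
})

test_that("DRNL channels are frequency tuned", {
  bank <- test_bank()
  j <- which.min(abs(bank$cf - 2000))
  resp <- function(f) {
    st <- synthesize_tone(f, 30, 0.2)
    bm <- anloud:::drnl_channel_trace(apply_outer_middle_ear(st), bank, j)
    sqrt(mean(bm[-seq_len(2000)]^2))
  }
  on_cf <- resp(bank$cf[j])
  off_cf <- resp(bank$cf[j] / 3)
  expect_gt(on_cf / off_cf, 10)
})

test_that("filterbank output is deterministic and rejects empty banks", {
  bank <- test_bank()
  st <- synthesize_tone(1000, 50, 0.1)
  x <- apply_outer_middle_ear(st)
  expect_identical(apply_drnl(x, bank), apply_drnl(x, bank))
  empty <- bank
  empty$channels <- list()
  expect_error(apply_drnl(x, empty), "no channels")
})
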