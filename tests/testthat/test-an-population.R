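test_that("fiber class structure: SR targets and opposed thresholds", {
  fb <- test_model()$fibers
  cl <- fb$classes
  expect_identical(cl$name,
                   c("low-threshold", "medium-threshold", "high-threshold"))
  expect_equal(cl$target_sr, c(35, 8, 2))
  # thresholds ordered oppositely to spontaneous rates
  expect_true(all(diff(cl$activation_threshold) > 0))
  expect_true(all(diff(cl$target_sr) < 0))
  expect_error(fiber_class_params(c(3, 2, 1), c(1, 1, 1)))
})

test_that("spontaneous rates hit the class targets under the probe tone", {
  mdl <- test_model()
  sp <- mdl$spont # 1 kHz at -10 dB SPL, spiking, seeded
  means <- unname(rowMeans(sp$rates))
  expect_equal(means, c(35, 8, 2), tolerance = 0.10)
  expect_gt(sum(sp$rates), 0)
  expect_true(all(sp$rates >= 0))
  expect_identical(dim(sp$rates), c(3L, mdl$bank$n_channels))
  # a different seed stays within sampling error of the targets
  sp2 <- measure_spontaneous(mdl, seed = 4242, duration = 4)
  expect_equal(unname(rowMeans(sp2$rates)), c(35, 8, 2), tolerance = 0.15)
  # rate mode returns the targets up to the sub-percent residual drive the
  # -10 dB probe tone leaves in the on-frequency channels
  sp3 <- measure_spontaneous(mdl, mode = "rate", duration = 1)
  expect_equal(unname(rowMeans(sp3$rates)), c(35, 8, 2), tolerance = 0.02)
})

test_that("same seed and input give identical spiking responses", {
  mdl <- test_model()
  st <- synthesize_tone(1000, 40, 0.6)
  bm <- apply_drnl(apply_outer_middle_ear(st), mdl$bank)
  r1 <- an_respond(bm, mdl$fibers, mdl$bank$cf, seed = 11, mode = "spiking")
  r2 <- an_respond(bm, mdl$fibers, mdl$bank$cf, seed = 11, mode = "spiking")
  expect_identical(r1$rates, r2$rates)
  r3 <- an_respond(bm, mdl$fibers, mdl$bank$cf, seed = 12, mode = "spiking")
  expect_false(identical(r1$rates, r3$rates))
  expect_warning(
    an_respond(bm[seq_len(4410), , drop = FALSE], mdl$fibers, mdl$bank$cf,
               seed = 1, mode = "spiking"),
    "0.5 s")
})

test_that("zero noise current silences spontaneous firing", {
  fb <- test_model()$fibers
  dt <- 1 / fb$sample_rate
  for (k in 1:3) {
    r <- anloud:::spont_rate_estimate(fb$classes$activation_threshold[k],
                                      0, fb$tau, fb$t_ref, dt, duration = 2)
    expect_identical(r, 0)
  }
})

test_that("spontaneous rate is monotone in the noise-current level", {
  fb <- test_model()$fibers
  dt <- 1 / fb$sample_rate
  theta <- fb$classes$activation_threshold[1]
  sigmas <- theta * c(0.2, 0.4, 0.8, 1.6)
  set.seed(1)
  rates <- vapply(sigmas, function(s)
    anloud:::spont_rate_estimate(theta, s, fb$tau, fb$t_ref, dt, 20), 0)
  expect_true(all(diff(rates) > 0))
})

test_that("rate-level functions: monotone, ordered saturation by class", {
  mdl <- test_model()
  lv <- seq(0, 100, 10)
  j <- which.min(abs(mdl$bank$cf - 1000))
  rl <- vapply(lv, function(L) {
    st <- synthesize_tone(1000, L, 0.5)
    anloud:::periphery_rates(st, mdl$bank, mdl$fibers, mdl$ome,
                             mode = "rate")[, j]
  }, numeric(3))
  # monotone non-decreasing in level for every class
  for (k in 1:3) expect_true(all(diff(rl[k, ]) > -1e-9))
  # the low-threshold class reaches half-saturation at a lower level
  half_level <- function(k) {
    r <- rl[k, ]
    lv[which(r >= r[1] + 0.5 * (max(r) - r[1]))[1]]
  }
  expect_lt(half_level(1), half_level(2))
  expect_lt(half_level(2), half_level(3))
})

test_that("spiking and rate modes agree on class rate-level functions", {
  mdl <- test_model()
  probes <- c(500, 1000, 2000, 4000)
  lv <- c(20, 50, 80)
  for (f in probes) {
    j <- which.min(abs(mdl$bank$cf - f))
    for (L in lv) {
      st <- synthesize_tone(f, L, 2) # 2 s keeps sampling noise below the bound
      spk <- anloud:::periphery_rates(st, mdl$bank, mdl$fibers, mdl$ome,
                                      seed = seed_for(1, f, L),
                                      mode = "spiking")
      rt <- anloud:::periphery_rates(st, mdl$bank, mdl$fibers, mdl$ome,
                                     mode = "rate")
      # class means over the whole bank (single-fiber rates are noisy)
      ms <- rowMeans(spk)
      mr <- rowMeans(rt)
      expect_lt(max(abs(ms - mr) / pmax(mr, 5)), 0.10)
    }
  }
})

test_that("calibration rejects a degenerate drive curve", {
  broken <- test_bank()
  broken$stapes_scale <- 0 # silent periphery: no drive at any level
  expect_error(calibrate_fiber_classes(broken, seed = 1), "calibration")
})
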