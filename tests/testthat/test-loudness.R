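test_that("sone formula: calibration point, zero clamp, direct evaluation", {
  cal <- loudness_calibration(x = 1.61, reference_sum = 1000,
                              spont_sum = 2884)
  ref <- toy_response(matrix(c(40, 10, 3), 3, 10),
                      spont = matrix(c(35, 8, 2), 3, 10))
  # baseline-subtracted sum of ref is (5+2+1)*10 = 80
  expect_equal(loudness_sones(ref, cal), (80 / 1000)^1.61)
  base <- toy_response(matrix(c(35, 8, 2), 3, 10))
  expect_identical(loudness_sones(base, cal), 0)
  twice <- toy_response(matrix(c(35, 8, 2), 3, 10) + 200,
                        spont = matrix(c(35, 8, 2), 3, 10))
  cal2 <- loudness_calibration(x = 1.61, reference_sum = 3000,
                               spont_sum = 2884)
  expect_equal(loudness_sones(twice, cal2), (6000 / 3000)^1.61)
  expect_equal((2)^1.61, loudness_sones(twice, cal2))
})

test_that("exponent fit recovers constructed power laws", {
  lv <- seq(30, 90, 10)
  # identity: responses already equal the sone targets
  expect_equal(calibrate_x(lv, sone_law(lv)), 1, tolerance = 1e-3)
  # inverted power law with known exponent
  r <- sone_law(lv)^(1 / 1.5)
  expect_equal(calibrate_x(lv, r), 1.5, tolerance = 0.01)
  r2 <- sone_law(lv)^(1 / 2.2)
  expect_equal(calibrate_x(lv, r2), 2.2, tolerance = 0.01)
  expect_error(calibrate_x(lv, rev(r)), "increasing")
  expect_error(calibrate_x(lv, c(r[1:6], -1)), "increasing")
})

test_that("equal-loudness search inverts activity curves correctly", {
  # monotone synthetic activity with a known crossing at 57.3 dB
  f <- function(L) 3000 + 40 * (L + 20)^1.3
  curve <- data.frame(level = seq(-20, 130, 2), activity = f(seq(-20, 130, 2)))
  target <- f(57.3)
  hit <- find_equal_loudness_level(curve, target)
  expect_identical(hit$flag, "ok")
  # dense-grid brute-force oracle at 0.1 dB
  dense <- seq(-20, 130, 0.1)
  oracle <- dense[which(f(dense) >= target)[1]]
  expect_lt(abs(hit$level - oracle), 0.25)
  expect_lt(abs(hit$level - 57.3), 0.25)
  # self-match on a grid point is exact
  exact <- find_equal_loudness_level(curve, f(40))
  expect_equal(exact$level, 40, tolerance = 1e-9)
  # unreachable targets are flagged, not silently returned
  expect_identical(find_equal_loudness_level(curve, f(-20) - 1)$flag,
                   "below-range")
  expect_identical(find_equal_loudness_level(curve, f(130) + 1)$flag,
                   "above-range")
})

test_that("contour set has the printed levels and the reference identity", {
  grid <- test_grid()
  elcs <- compute_elc_set(grid, g_hc = 1)
  expect_length(elcs$contours, 18L)
  expect_setequal(vapply(elcs$contours, `[[`, 0, "phon_level"),
                  c(seq(-10, 130, 10), -5, -2, 2))
  for (cc in elcs$contours) {
    ref <- cc$points[cc$points$frequency == 1000, ]
    expect_equal(ref$level_db_spl, cc$phon_level)
  }
  df <- elc_as_data_frame(elcs)
  expect_identical(nrow(df), 18L * 9L)
})

test_that("summed activity is monotone and contours do not cross", {
  grid <- test_grid()
  sa <- grid_summed_activity(grid, g_hc = 1)
  for (cv in sa$curves) expect_true(all(diff(cv$activity) > -1e-9))
  elcs <- compute_elc_set(grid, g_hc = 1)
  lvl <- vapply(elcs$contours, function(cc) cc$points$level_db_spl,
                numeric(9))
  for (f in seq_len(9)) {
    v <- lvl[f, ]
    v <- v[!is.na(v)]
    expect_true(all(diff(v) > 0))
  }
})

test_that("model dB HL is the subtraction of the 2-phon contour", {
  grid <- test_grid()
  elcs <- compute_elc_set(grid, g_hc = 1)
  hl <- to_model_hl(elcs)
  two <- hl$contours[[which(vapply(hl$contours, `[[`, 0, "phon_level") == 2)]]
  ref2 <- elc_levels(elcs, 2)
  # the 2-phon contour maps to 0 dB model HL wherever it is defined (at a
  # few hyper-sensitive frequencies its own level lies below the search
  # floor and the flag propagates)
  ok <- !is.na(ref2)
  expect_gte(sum(ok), 6)
  expect_equal(two$points$level_db_model_hl[ok], rep(0, sum(ok)))
  p40 <- hl$contours[[which(vapply(hl$contours, `[[`, 0, "phon_level") == 40)]]
  expect_equal(p40$points$level_db_model_hl[ok],
               (p40$points$level_db_spl - ref2)[ok])
  # at 1 kHz: 40-phon model HL = 40 - (2-phon level at 1 kHz) = 38
  expect_equal(p40$points$level_db_model_hl[p40$points$frequency == 1000],
               40 - 2)
  noref <- compute_elc_set(grid, g_hc = 1, reference_levels = c(10, 40))
  expect_error(to_model_hl(noref), "2-phon")
})

test_that("contour search matches a 0.1-dB brute-force grid", {
  mdl <- test_model()
  grid <- test_grid()
  sa <- grid_summed_activity(grid, g_hc = 1)
  ref <- anloud:::reference_activity_at(sa, 40)
  k <- which(grid$frequencies == 500)
  hit <- find_equal_loudness_level(sa$curves[[k]], ref)
  expect_identical(hit$flag, "ok")
  dense <- seq(hit$level - 4, hit$level + 4, by = 0.1)
  act <- vapply(dense, function(L)
    model_summed_activity(mdl, 500, L, g_hc = 1, mode = "rate"), 0)
  oracle <- dense[which(act >= ref)[1]]
  expect_lt(abs(hit$level - oracle), 1)
})

test_that("loudness doubles when a 1-kHz tone rises from 50 to 60 dB", {
  mdl <- test_model()
  r50 <- model_tone_response(mdl, 1000, 50, mode = "rate", g_hc = 1)
  r60 <- model_tone_response(mdl, 1000, 60, mode = "rate", g_hc = 1)
  s50 <- loudness_sones(r50, mdl$loudness)
  s60 <- loudness_sones(r60, mdl$loudness)
  expect_gt(s60 / s50, 2 * 0.85)
  expect_lt(s60 / s50, 2 * 1.15)
})
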