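test_that("healthy gain: identity, scalar multiply, weighted-sum oracle", {
  r <- toy_response(matrix(runif(3 * 8, 10, 200), nrow = 3))
  expect_equal(apply_healthy_gain(r, quadratic_gain(1, 0, 0))$rates, r$rates)
  expect_equal(apply_healthy_gain(r, quadratic_gain(2, 0, 0))$rates,
               2 * r$rates)
  g <- quadratic_gain(1, 0.01, 15)
  out <- apply_healthy_gain(r, g)
  # brute-force recomputation of the weighted sum, fiber by fiber
  gcf <- eval_gain(g, r$cf)
  manual <- sum(vapply(seq_along(r$cf), function(j)
    sum(gcf[j] * r$rates[, j]), 0))
  expect_equal(sum(out$rates), manual, tolerance = 1e-12)
  expect_equal(out$spont, r$spont * rep(gcf, each = 3))
})

test_that("quadratic gains are clipped at a positive floor with a warning", {
  g <- quadratic_gain(-5, 0.001, 20)
  expect_warning(v <- eval_gain(g, c(500, 1000, 2000)), "floor")
  expect_true(all(v > 0))
  r <- toy_response(matrix(50, nrow = 3, ncol = 4))
  expect_error(apply_healthy_gain(r, -1), "positive")
})

test_that("there are exactly eight hyperacusis gain variants", {
  v <- all_gain_variants()
  expect_length(v, 8L)
  flags <- t(vapply(v, function(s) c(s$form, s$scope, s$frequency),
                    character(3)))
  expect_identical(nrow(unique(as.data.frame(flags))), 8L)
  expect_true(all(vapply(v, function(s) s$z, 0) == 1.1))
})

test_that("supra-threshold gain leaves spontaneous-only responses alone", {
  sp <- matrix(c(35, 8, 2), nrow = 3, ncol = 6)
  r <- toy_response(sp, spont = sp)
  for (form in c("linear", "power-law")) {
    spec <- hyperacusis_gain_spec(form, "supra-threshold", "independent",
                                  g = 3)
    out <- apply_hyperacusis_gain(r, spec, g_hc = 1, r_max = c(250, 250, 250))
    expect_equal(out$rates, sp, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(out$spont, sp, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("linear sub-threshold gain with g = 1 equals healthy-only output", {
  r <- toy_response(matrix(runif(3 * 6, 1, 300), nrow = 3))
  g_hc <- quadratic_gain(1, 0.02, 12)
  spec <- hyperacusis_gain_spec("linear", "sub-threshold", "independent",
                                g = 1)
  expect_equal(apply_hyperacusis_gain(r, spec, g_hc = g_hc)$rates,
               apply_healthy_gain(r, g_hc)$rates, tolerance = 1e-12)
})

test_that("power-law gain saturates at g_max and never exceeds it", {
  r_max <- c(250, 250, 250)
  rates <- matrix(c(250, 250, 250, 100, 40, 10), nrow = 3)
  r <- toy_response(rates, spont = matrix(0.1, 3, 2))
  spec <- hyperacusis_gain_spec("power-law", "sub-threshold", "independent",
                                g = 4)
  out <- apply_hyperacusis_gain(r, spec, g_hc = 1, r_max = r_max)
  # at R = R_max the gain is exactly g_max
  expect_equal(unname(out$rates[, 1]), 4 * rates[, 1], tolerance = 1e-12)
  # everywhere the effective gain is <= g_max
  eff <- out$rates / rates
  expect_true(all(eff <= 4 + 1e-12))
  expect_true(all(eff[, 2] < 4))
  expect_error(apply_hyperacusis_gain(r, spec, g_hc = 1), "r_max")
})

test_that("frequency-independent variants equal quadratic ones with b = 0", {
  r <- toy_response(matrix(runif(3 * 5, 5, 200), nrow = 3))
  for (form in c("linear", "power-law"))
    for (scope in c("sub-threshold", "supra-threshold")) {
      s1 <- hyperacusis_gain_spec(form, scope, "independent", g = 2.5)
      s2 <- hyperacusis_gain_spec(form, scope, "quadratic",
                                  g = quadratic_gain(2.5, 0, 0))
      o1 <- apply_hyperacusis_gain(r, s1, g_hc = 1, r_max = c(250, 250, 250))
      o2 <- apply_hyperacusis_gain(r, s2, g_hc = 1, r_max = c(250, 250, 250))
      expect_equal(o1$rates, o2$rates, tolerance = 1e-12)
    }
})

test_that("all variants are monotone in the input rates", {
  set.seed(5)
  base <- matrix(runif(3 * 6, 5, 180), nrow = 3)
  higher <- base + matrix(runif(3 * 6, 0, 40), nrow = 3)
  r1 <- toy_response(base)
  r2 <- toy_response(higher)
  for (spec in all_gain_variants()) {
    spec$g <- if (inherits(spec$g, "quadratic_gain"))
      quadratic_gain(2, 0.005, 10) else 2
    o1 <- apply_hyperacusis_gain(r1, spec, g_hc = 1,
                                 r_max = c(300, 300, 300))
    o2 <- apply_hyperacusis_gain(r2, spec, g_hc = 1,
                                 r_max = c(300, 300, 300))
    expect_gte(sum(o2$rates) - sum(o1$rates), 0)
  }
})

test_that("sub-threshold linear gain raises baseline; supra does not", {
  sp <- matrix(c(35, 8, 2), nrow = 3, ncol = 6)
  r <- toy_response(sp, spont = sp)
  sub <- apply_hyperacusis_gain(
    r, hyperacusis_gain_spec("linear", "sub-threshold", "independent", g = 2))
  supra <- apply_hyperacusis_gain(
    r, hyperacusis_gain_spec("linear", "supra-threshold", "independent",
                             g = 2))
  expect_equal(sum(sub$spont), 2 * sum(sp))
  expect_equal(sum(supra$spont), sum(sp))
})

test_that("gain specs round-trip through YAML bit-exactly", {
  path <- withr::local_tempfile(fileext = ".yaml")
  s1 <- hyperacusis_gain_spec("power-law", "supra-threshold", "quadratic",
                              g = quadratic_gain(2.25, 0.0125, 17.5), z = 1.1)
  write_gain_spec(s1, path)
  s2 <- read_gain_spec(path)
  expect_identical(s2$form, s1$form)
  expect_identical(s2$scope, s1$scope)
  expect_identical(unclass(s2$g), unclass(s1$g))
  expect_identical(s2$z, s1$z)
  s3 <- hyperacusis_gain_spec("linear", "sub-threshold", "independent",
                              g = 3.5)
  write_gain_spec(s3, path)
  expect_identical(unclass(read_gain_spec(path)),
                   unclass(s3))
})

test_that("variant constructors validate their arguments", {
  expect_error(hyperacusis_gain_spec("linear", "sub-threshold", "quadratic",
                                     g = 2), "quadratic_gain")
  expect_error(hyperacusis_gain_spec("linear", "sub-threshold", "independent",
                                     g = quadratic_gain(1, 0, 0)), "scalar")
  expect_error(apply_hyperacusis_gain(
    toy_response(matrix(1, 3, 2), spont = NULL),
    hyperacusis_gain_spec("linear", "bogus", "independent", g = 1)))
})
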