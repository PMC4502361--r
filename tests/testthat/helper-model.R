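# Shared, lazily built fixtures: one calibrated desk-profile model, its
# response grid and the healthy-gain fit are reused across test files.
the <- new.env(parent = emptyenv())

test_model <- function() {
  if (is.null(the$model))
    the$model <- calibrate_model(build_model("desk", seed = 42))
  the$model
}

test_grid <- function() {
  if (is.null(the$grid))
    the$grid <- compute_response_grid(test_model())
  the$grid
}

test_healthy_fit <- function() {
  if (is.null(the$healthy))
    the$healthy <- fit_healthy_gain(make_control_table(), test_grid())
  the$healthy
}

test_variant_report <- function() {
  if (is.null(the$report)) {
    patient <- make_patient_table()
    the$report <- compare_variants(patient, test_grid(), test_healthy_fit(),
                                   weights = ceiling_weights(patient))
  }
  the$report
}

# Small filterbank for unit tests that do not need the calibrated model.
test_bank <- function() {
  if (is.null(the$bank))
    the$bank <- make_human_filterbank(32, 40, 13000,
                                      warn_extrapolation = FALSE)
  the$bank
}

# A tiny an_response with hand-set rates for gain-stage arithmetic tests.
toy_response <- function(rates, spont = NULL, cf = NULL) {
  nch <- ncol(rates)
  if (is.null(cf)) cf <- erb_space(125, 8000, nch)
  if (is.null(spont)) spont <- matrix(c(35, 8, 2), nrow = 3, ncol = nch)
  anloud:::new_an_response(rates, spont, cf, mode = "rate", duration = 1)
}
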