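#' Gain stage: healthy-control gain and hyperacusis gain variants
#'
#' Perceived loudness in the model is read out from the summed activity of
#' the gain-stage output. A frequency-dependent "healthy control" gain
#' `g_hc(cf) = a + b (cf - c)^2` weights every fiber's rate to reproduce
#' normal loudness perception. A second, "hyperacusis" gain can then be
#' applied; it is one of eight variants spanned by three binary choices:
#' linear vs power-law form, sub- vs supra-threshold scope, and
#' frequency-independent vs quadratic frequency dependence.
#'
#' * linear: `R' = g_l(cf) g_hc(cf) R`
#' * power-law: `g_p = (R / R_max)^z g_max(cf)`; `R' = g_p g_hc R`
#'   (so `g_p <= g_max` always, since `R <= R_max`)
#' * supra-threshold scope replaces the inner product with
#'   `(max(0, R - R_sp) g + R_sp) g_hc`, leaving spontaneous activity
#'   untouched.
#'
#' @name gain_stage
NULL

GAIN_FLOOR <- 1e-3

#' Quadratic frequency-dependent gain
#'
#' `g(cf) = a + b (u(cf) - c)^2` where `u` is the ERB-number of the
#' characteristic frequency by default (so curvature is well behaved over
#' three decades of frequency), or the raw frequency in Hz.
#'
#' @param a Offset (gain at the vertex).
#' @param b Curvature; `b = 0` gives a frequency-independent gain.
#' @param c Vertex position, in the units of `units`.
#' @param units `"erb"` (default) or `"hz"`.
#' @return A `quadratic_gain` object.
#' @export
quadratic_gain <- function(a, b = 0, c = 0, units = c("erb", "hz")) {
  units <- match.arg(units)
  structure(list(a = a, b = b, c = c, units = units),
            class = "quadratic_gain")
}

#' Evaluate a gain at a set of characteristic frequencies
#'
#' Scalars are recycled; quadratic gains are evaluated and clipped at a
#' small positive floor (with a warning) so that gains never negate rates.
#'
#' @param gain A scalar or a [quadratic_gain()].
#' @param cf Characteristic frequencies in Hz.
#' @return Numeric vector of per-channel gains.
#' @export
eval_gain <- function(gain, cf) {
  if (is.numeric(gain) && length(gain) == 1L)
    return(rep(gain, length(cf)))
  stopifnot(inherits(gain, "quadratic_gain"))
  u <- if (gain$units == "erb") erb_number(cf) else cf
  g <- gain$a + gain$b * (u - gain$c)^2
  if (any(g < GAIN_FLOOR)) {
    warning("quadratic gain fell below the positive floor (",
            GAIN_FLOOR, ") for some channels; clipped", call. = FALSE)
    g <- pmax(g, GAIN_FLOOR)
  }
  g
}

#' Hyperacusis gain variant specification
#'
#' Encodes exactly one of the eight candidate gain mechanisms.
#'
#' @param form `"linear"` or `"power-law"`.
#' @param scope `"sub-threshold"` (gain multiplies all activity, including
#'   spontaneous) or `"supra-threshold"` (gain applies only to the evoked
#'   component above the spontaneous baseline).
#' @param frequency `"independent"` (scalar gain) or `"quadratic"`.
#' @param g Scalar gain (`g_l` or `g_max`) when frequency-independent, or a
#'   [quadratic_gain()] when frequency-dependent.
#' @param z Power-law exponent (fixed default 1.1).
#' @return A `hyperacusis_gain_spec` object.
#' @export
hyperacusis_gain_spec <- function(form = c("linear", "power-law"),
                                  scope = c("supra-threshold",
                                            "sub-threshold"),
                                  frequency = c("independent", "quadratic"),
                                  g = 1, z = 1.1) {
  form <- match.arg(form)
  scope <- match.arg(scope)
  frequency <- match.arg(frequency)
  if (frequency == "quadratic" && !inherits(g, "quadratic_gain"))
    stop("a quadratic variant needs a quadratic_gain for g")
  if (frequency == "independent" && !(is.numeric(g) && length(g) == 1L))
    stop("a frequency-independent variant needs a scalar g")
  structure(list(form = form, scope = scope, frequency = frequency,
                 g = g, z = z),
            class = "hyperacusis_gain_spec")
}

#' @export
print.hyperacusis_gain_spec <- function(x, ...) {
  gtxt <- if (inherits(x$g, "quadratic_gain"))
    sprintf("a=%.4g b=%.4g c=%.4g (%s)", x$g$a, x$g$b, x$g$c, x$g$units)
  else sprintf("g=%.4g", x$g)
  cat(sprintf("<hyperacusis_gain_spec> %s, %s, frequency-%s; %s; z=%.3g\n",
              x$form, x$scope, x$frequency, gtxt, x$z))
  invisible(x)
}

#' All eight hyperacusis gain variant templates
#' @return Named list of eight `hyperacusis_gain_spec` templates (unit gain).
#' @export
all_gain_variants <- function() {
  out <- list()
  for (form in c("linear", "power-law"))
    for (scope in c("supra-threshold", "sub-threshold"))
      for (freq in c("independent", "quadratic")) {
        g <- if (freq == "quadratic") quadratic_gain(1, 0, 0) else 1
        key <- paste(form, scope, freq, sep = "/")
        out[[key]] <- hyperacusis_gain_spec(form, scope, freq, g = g)
      }
  out
}

# Core gain-stage arithmetic on raw matrices (3 classes x channels).
# Returns the transformed rates and the transformed no-stimulus baseline.
apply_gain_stage_matrices <- function(rates, spont, cf, ghc_cf, spec = NULL,
                                      r_max = NULL) {
  nch <- ncol(rates)
  Ghc <- matrix(ghc_cf, nrow = 3, ncol = nch, byrow = TRUE)
  if (is.null(spec))
    return(list(rates = rates * Ghc, spont = spont * Ghc))
  gcf <- eval_gain(spec$g, cf)
  G <- matrix(gcf, nrow = 3, ncol = nch, byrow = TRUE)
  if (spec$form == "power-law") {
    if (is.null(r_max)) stop("power-law gain needs per-class r_max")
    Rm <- matrix(r_max, nrow = 3, ncol = nch)
    G <- (pmin(rates, Rm) / Rm)^spec$z * G
  }
  if (spec$scope == "sub-threshold") {
    Gsp <- G
    if (spec$form == "power-law") {
      Rm <- matrix(r_max, nrow = 3, ncol = nch)
      Gsp <- (pmin(spont, Rm) / Rm)^spec$z *
        matrix(gcf, nrow = 3, ncol = nch, byrow = TRUE)
    }
    list(rates = G * Ghc * rates, spont = Gsp * Ghc * spont)
  } else {
    list(rates = (pmax(0, rates - spont) * G + spont) * Ghc,
         spont = spont * Ghc)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply the healthy-control gain to an AN response
#'
#' Every fiber's rate, and its spontaneous baseline, is multiplied by
#' `g_hc(cf)`; the healthy gain is a plain multiplicative weight.
#'
#' @param response An `an_response`.
#' @param g_hc A [quadratic_gain()] or positive scalar.
#' @return The gained `an_response`.
#' @export
apply_healthy_gain <- function(response, g_hc) {
  ghc_cf <- eval_gain(g_hc, response$cf)
  if (any(ghc_cf <= 0)) stop("healthy gain must be positive over the bank")
  out <- apply_gain_stage_matrices(response$rates, response$spont,
                                   response$cf, ghc_cf)
  response$rates <- out$rates
  response$spont <- out$spont
  response
}

#' Apply a hyperacusis gain variant (on top of the healthy gain)
#'
#' Implements the selected variant's formula per fiber, with the healthy
#' control gain `g_hc` as the outer multiplicative factor.
#'
#' @param response An `an_response` (raw AN rates, before any gain).
#' @param spec A [hyperacusis_gain_spec()].
#' @param g_hc Healthy-control gain ([quadratic_gain()] or scalar).
#' @param r_max Per-class saturation rates (length 3), required for
#'   power-law variants.
#' @return The gained `an_response`.
#' @export
apply_hyperacusis_gain <- function(response, spec, g_hc = 1, r_max = NULL) {
  stopifnot(inherits(spec, "hyperacusis_gain_spec"))
  if (spec$scope == "supra-threshold" && is.null(response$spont))
    stop("supra-threshold gain needs the spontaneous baseline")
  ghc_cf <- eval_gain(g_hc, response$cf)
  out <- apply_gain_stage_matrices(response$rates, response$spont,
                                   response$cf, ghc_cf, spec, r_max)
  response$rates <- out$rates
  response$spont <- out$spont
  response
}

#' Serialize a hyperacusis gain spec to YAML
#' @param spec A [hyperacusis_gain_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gain_spec <- function(spec, path) {
  obj <- list(form = spec$form, scope = spec$scope,
              frequency = spec$frequency, z = spec$z)
  if (inherits(spec$g, "quadratic_gain"))
    obj$g <- list(a = spec$g$a, b = spec$g$b, c = spec$g$c,
                  units = spec$g$units)
  else obj$g <- spec$g
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a hyperacusis gain spec from YAML
#' @param path File written by [write_gain_spec()].
#' @return A `hyperacusis_gain_spec`.
#' @export
read_gain_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  g <- if (is.list(obj$g))
    quadratic_gain(obj$g$a, obj$g$b, obj$g$c, units = obj$g$units)
  else obj$g
  hyperacusis_gain_spec(obj$form, obj$scope, obj$frequency, g = g, z = obj$z)
}
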