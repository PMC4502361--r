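#' Loudness in sones and equal-loudness contours from AN activity
#'
#' The model's central assumption is that perceived loudness is proportional
#' to the summed activity of all auditory-nerve fibers (after the gain
#' stage). Loudness in sones is computed from the baseline-subtracted summed
#' activity, normalized to the response to a 1-kHz tone at 40 dB SPL and
#' raised to a calibrated exponent `x`:
#' `Ldn(f, L) = ((sum R - R_sp) / (sum R(1 kHz, 40 dB) - R_sp))^x`.
#' Equal-loudness contours (ELCs) are found by searching, per frequency, for
#' the level that evokes the same total activity as a 1-kHz reference tone.
#'
#' @name loudness
NULL

#' Test frequencies for equal-loudness contours (Hz)
#' @export
ELC_FREQUENCIES <- c(125, 250, 500, 1000, 2000, 3000, 4000, 6000, 8000)

#' Reference 1-kHz levels for the standard contour set (dB SPL)
#' @export
ELC_REFERENCE_LEVELS <- sort(c(seq(-10, 130, by = 10), -5, -2, 2))

#' Sone value of a 1-kHz tone at a given level
#'
#' The sone-scale law for 1-kHz tones: 1 sone at 40 dB SPL, doubling for
#' every 10 dB (stand-in for the tabulated loudness standard).
#'
#' @param level Level in dB SPL.
#' @return Loudness in sones.
#' @export
sone_law <- function(level) 2^((level - 40) / 10)

# ---- Loudness calibration and evaluation ------------------------------------

#' Loudness calibration container
#'
#' @param x Loudness exponent.
#' @param reference_sum Baseline-subtracted summed activity of the 1-kHz,
#'   40-dB SPL reference (sp/s), in the gain context of the responses the
#'   calibration will be applied to.
#' @param spont_sum Summed spontaneous activity (sp/s), same context.
#' @return A `loudness_calibration` object.
#' @export
loudness_calibration <- function(x, reference_sum, spont_sum) {
  stopifnot(reference_sum > 0)
  structure(list(x = x, reference_sum = reference_sum,
                 spont_sum = spont_sum),
            class = "loudness_calibration")
}

#' Loudness of an AN response in sones
#'
#' Applies the calibrated sone formula. Responses whose summed activity lies
#' below the spontaneous baseline (possible by chance in spiking mode) clamp
#' to 0 sones.
#'
#' @param response An `an_response` (gain stage already applied if any).
#' @param cal A [loudness_calibration()] computed in the same gain context.
#' @return Loudness in sones.
#' @export
loudness_sones <- function(response, cal) {
  num <- sum(response$rates) - sum(response$spont)
  if (num <= 0) return(0)
  (num / cal$reference_sum)^cal$x
}

#' Fit the loudness exponent
#'
#' Least-squares fit (minimizing the mean squared error in sones) of the
#' exponent `x` such that the normalized baseline-subtracted summed
#' response raised to `x` matches the sone targets for 1-kHz tones.
#'
#' @param levels Tone levels in dB SPL (>= 5 values spanning 30-90
#'   recommended).
#' @param evoked Baseline-subtracted summed responses at those levels
#'   (sp/s); must be positive and strictly increasing.
#' @param sone_targets Target loudness in sones (default: [sone_law()]).
#' @param ref_level Level whose response normalizes the ratio (default 40).
#' @return Fitted exponent `x`.
#' @export
calibrate_x <- function(levels, evoked, sone_targets = sone_law(levels),
                        ref_level = 40) {
  stopifnot(length(levels) == length(evoked))
  o <- order(levels)
  levels <- levels[o]; evoked <- evoked[o]; sone_targets <- sone_targets[o]
  if (any(evoked <= 0) || any(diff(evoked) <= 0))
    stop("summed responses must be positive and strictly increasing in level")
  ref <- stats::approx(levels, evoked, xout = ref_level, rule = 2)$y
  N <- evoked / ref
  stats::optimize(function(x) mean((N^x - sone_targets)^2),
                  interval = c(0.2, 6))$minimum
}

# ---- Response grid ----------------------------------------------------------

# Step policy for contour searches: a 10-dB coarse grid over the full range,
# plus a 2-dB fine grid bracketing the model hearing threshold (where the
# evoked response first exceeds 1% of the spontaneous sum).
grid_levels_for <- function(coarse_levels, evoked_frac) {
  idx <- which(evoked_frac > 0.01)
  if (length(idx) == 0) return(coarse_levels)
  l1 <- coarse_levels[idx[1]]
  fine <- seq(max(min(coarse_levels), l1 - 12), l1 + 10, by = 2)
  sort(unique(c(coarse_levels, fine)))
}

#' Precompute auditory-nerve responses on a frequency-by-level grid
#'
#' Runs the periphery and AN population for pure tones at each test
#' frequency over a level grid (10-dB steps over the full range, refined to
#' 2-dB steps around the model hearing threshold). Per-fiber rates are
#' independent of the gain stage, so a single grid supports every gain
#' configuration: contour searches and gain fitting all operate on this
#' cache. Each (frequency, level) evaluation uses its own derived seed so
#' results are reproducible point-wise.
#'
#' @param model A calibrated [build_model()] object.
#' @param frequencies Test frequencies in Hz (must include 1000).
#' @param level_range Search range in dB SPL (default -20 to 130).
#' @param seed Base seed (default: the model's).
#' @param mode `"rate"` (deterministic, default for the desk profile) or
#'   `"spiking"`.
#' @return An `an_response_grid` object.
#' @export
compute_response_grid <- function(model, frequencies = ELC_FREQUENCIES,
                                  level_range = c(-20, 130),
                                  seed = model$seed,
                                  mode = model$mode) {
  stopifnot(1000 %in% frequencies, model$calibrated)
  coarse <- seq(level_range[1], level_range[2], by = 10)
  spont <- grid_spont(model, mode)
  spont_sum <- sum(spont)
  eval_point <- function(f, L) {
    st <- synthesize_tone(f, L, model$duration,
                          sample_rate = model$bank$sample_rate)
    periphery_rates(st, model$bank, model$fibers, model$ome,
                    seed = seed_for(seed, f, L), mode = mode)
  }
  per_freq <- lapply(frequencies, function(f) {
    coarse_rates <- lapply(coarse, function(L) eval_point(f, L))
    evoked <- vapply(coarse_rates, function(r) sum(r) - spont_sum, 0)
    levels <- grid_levels_for(coarse, evoked / spont_sum)
    extra <- setdiff(levels, coarse)
    rates <- vector("list", length(levels))
    rates[match(coarse, levels)] <- coarse_rates
    for (L in extra) rates[[match(L, levels)]] <- eval_point(f, L)
    arr <- array(unlist(rates),
                 dim = c(3, model$bank$n_channels, length(levels)))
    list(levels = levels, rates = arr)
  })
  names(per_freq) <- as.character(frequencies)
  structure(list(frequencies = frequencies, data = per_freq, spont = spont,
                 cf = model$bank$cf, mode = mode, seed = seed,
                 duration = model$duration, r_max = model$fibers$r_max),
            class = "an_response_grid")
}

#' @export
print.an_response_grid <- function(x, ...) {
  cat(sprintf(
    "<an_response_grid> %d frequencies x %s levels, %d channels, mode '%s'\n",
    length(x$frequencies),
    paste(range(vapply(x$data, function(d) length(d$levels), 0L)),
          collapse = "-"),
    ncol(x$spont), x$mode))
  invisible(x)
}

# Spontaneous baseline matrix matching the evaluation mode.
grid_spont <- function(model, mode) {
  if (mode == "rate")
    matrix(model$fibers$classes$target_sr, nrow = 3,
           ncol = model$bank$n_channels)
  else model$spont$rates
}

#' Summed gain-stage output on a response grid
#'
#' Applies the healthy gain (and optionally a hyperacusis variant) to every
#' cached response and returns, per frequency, the total summed activity as
#' a function of level, plus the no-stimulus baseline activity.
#'
#' @param grid An [compute_response_grid()] result.
#' @param g_hc Healthy-control gain ([quadratic_gain()] or scalar).
#' @param spec Optional [hyperacusis_gain_spec()].
#' @return A `summed_activity_set`: list with `curves` (per frequency, a
#'   data frame of `level`, `activity`) and `baseline` (sp/s).
#' @export
grid_summed_activity <- function(grid, g_hc = 1, spec = NULL) {
  ghc_cf <- eval_gain(g_hc, grid$cf)
  curves <- lapply(grid$data, function(d) {
    act <- vapply(seq_along(d$levels), function(i) {
      out <- apply_gain_stage_matrices(d$rates[, , i, drop = TRUE],
                                       grid$spont, grid$cf, ghc_cf,
                                       spec, grid$r_max)
      sum(out$rates)
    }, 0)
    data.frame(level = d$levels, activity = act)
  })
  base <- apply_gain_stage_matrices(grid$spont, grid$spont, grid$cf, ghc_cf,
                                    spec, grid$r_max)
  structure(list(curves = curves, baseline = sum(base$spont),
                 frequencies = grid$frequencies),
            class = "summed_activity_set")
}

# ---- Equal-loudness search --------------------------------------------------

#' Find the level matching a reference summed activity
#'
#' Returns the smallest level at which the (linearly interpolated) summed
#' activity equals `reference_sum`. The interpolation is on activity versus
#' level, then inverted for the level.
#'
#' @param curve Data frame with columns `level` (dB SPL, increasing) and
#'   `activity` (sp/s), e.g. one element of
#'   [grid_summed_activity()]`$curves`.
#' @param reference_sum Target summed activity (sp/s).
#' @return List with `level` (dB SPL, `NA` if unreachable) and `flag`
#'   (`"ok"`, `"below-range"` if the target lies below the activity at the
#'   lowest searched level, `"above-range"` if above the highest).
#' @export
find_equal_loudness_level <- function(curve, reference_sum) {
  lv <- curve$level
  ac <- curve$activity
  if (reference_sum <= ac[1])
    return(list(level = NA_real_, flag = "below-range"))
  i <- which(ac >= reference_sum)
  i <- i[i > 1][1]
  if (is.na(i))
    return(list(level = NA_real_, flag = "above-range"))
  a0 <- ac[i - 1]; a1 <- ac[i]
  w <- if (a1 > a0) (reference_sum - a0) / (a1 - a0) else 0
  list(level = lv[i - 1] + w * (lv[i] - lv[i - 1]), flag = "ok")
}

#' Compute a set of equal-loudness contours
#'
#' One contour per 1-kHz reference level. The reference activity is always
#' taken from the healthy configuration (healthy gain only): the phon scale
#' is anchored to normal loudness perception, so a hyperacusis gain shifts
#' the contours relative to the fixed healthy reference.
#'
#' @param grid An [compute_response_grid()] result.
#' @param g_hc Healthy-control gain.
#' @param spec Optional [hyperacusis_gain_spec()]: compute the contours of
#'   the hyperacusis model against the healthy reference.
#' @param reference_levels 1-kHz reference levels in dB SPL (default: the
#'   standard 18-level set).
#' @return An `elc_set`: list of contours, each with `phon_level`,
#'   `reference_sum` and a `points` data frame
#'   (`frequency`, `level_db_spl`, `flag`).
#' @export
compute_elc_set <- function(grid, g_hc = 1, spec = NULL,
                            reference_levels = ELC_REFERENCE_LEVELS) {
  healthy <- grid_summed_activity(grid, g_hc)
  target <- if (is.null(spec)) healthy
            else grid_summed_activity(grid, g_hc, spec)
  ref_curve <- healthy$curves[["1000"]]
  contours <- lapply(reference_levels, function(P) {
    T <- stats::approx(ref_curve$level, ref_curve$activity, xout = P,
                       rule = 1)$y
    pts <- lapply(seq_along(grid$frequencies), function(k) {
      f <- grid$frequencies[k]
      if (is.null(spec) && f == 1000)
        return(data.frame(frequency = f, level_db_spl = P, flag = "ok"))
      hit <- find_equal_loudness_level(target$curves[[k]], T)
      data.frame(frequency = f, level_db_spl = hit$level, flag = hit$flag)
    })
    structure(list(phon_level = P, reference_sum = T,
                   points = do.call(rbind, pts)),
              class = "elc")
  })
  structure(list(contours = contours, frequencies = grid$frequencies,
                 reference_levels = reference_levels),
            class = "elc_set")
}

#' @export
print.elc_set <- function(x, ...) {
  cat(sprintf("<elc_set> %d contours at %d frequencies (%g-%g Hz)\n",
              length(x$contours), length(x$frequencies),
              min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

# Level (dB SPL) of one contour at each frequency, NA where flagged.
elc_levels <- function(elc_set, phon) {
  i <- which(vapply(elc_set$contours, function(cc) cc$phon_level, 0) == phon)
  if (length(i) != 1) stop("no contour at phon level ", phon)
  elc_set$contours[[i]]$points$level_db_spl
}

#' Convert contours from dB SPL to model dB HL
#'
#' Subtracts the 2-phon contour (which approximates the model hearing
#' threshold) from every contour at every frequency. For hyperacusis
#' contour sets the healthy set must be supplied as `reference` so the HL
#' axis stays anchored to normal hearing.
#'
#' @param elcs An `elc_set`.
#' @param reference `elc_set` providing the 2-phon contour (default:
#'   `elcs` itself).
#' @return `elcs` with a `level_db_model_hl` column added to every contour.
#' @export
to_model_hl <- function(elcs, reference = elcs) {
  phons <- vapply(reference$contours, function(cc) cc$phon_level, 0)
  if (!any(phons == 2))
    stop("the 2-phon contour is missing from the reference set")
  ht <- elc_levels(reference, 2)
  if (!identical(reference$frequencies, elcs$frequencies))
    stop("reference and target contour sets use different frequencies")
  elcs$contours <- lapply(elcs$contours, function(cc) {
    cc$points$level_db_model_hl <- cc$points$level_db_spl - ht
    cc
  })
  elcs$model_hl_reference <- ht
  elcs
}

#' Flatten a contour set to a data frame / CSV
#'
#' @param elcs An `elc_set` (optionally after [to_model_hl()]).
#' @param path Optional CSV output path.
#' @return Data frame with columns `phon_level`, `frequency_hz`,
#'   `level_db_spl`, `level_db_model_hl` (if present), `flags`.
#' @export
elc_as_data_frame <- function(elcs, path = NULL) {
  rows <- lapply(elcs$contours, function(cc) {
    df <- data.frame(phon_level = cc$phon_level,
                     frequency_hz = cc$points$frequency,
                     level_db_spl = cc$points$level_db_spl)
    if (!is.null(cc$points$level_db_model_hl))
      df$level_db_model_hl <- cc$points$level_db_model_hl
    df$flags <- cc$points$flag
    df
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
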