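#' Synthetic audiometric fixtures
#'
#' The clinical data the gain fitting targets (group-mean hearing thresholds
#' and loudness discomfort levels, LDLs) are emulated by a fixture
#' generator: a control cohort with normal thresholds and LDLs around
#' 100 dB HL, and a hyperacusis cohort whose LDLs are uniformly shifted
#' (default -20 dB, the typical decrease reported for hyperacusis patients)
#' while thresholds stay normal.
#'
#' @name fixtures
NULL

#' Clinical audiometric test frequencies (Hz)
#' @export
CLINICAL_FREQUENCIES <- c(125, 250, 500, 1000, 2000, 4000, 8000)

# Per-frequency audiometer output ceilings in dB HL (the low and high
# extremes of the clinical range have lower maximum output).
default_ceilings <- function(frequency) {
  ifelse(frequency <= 125, 90,
         ifelse(frequency <= 250, 110,
                ifelse(frequency >= 8000, 100, 120)))
}

#' Audiometric table
#'
#' @param frequency Frequencies in Hz (subset of the clinical set).
#' @param hearing_threshold Hearing thresholds in dB HL.
#' @param ldl Loudness discomfort levels in dB HL; must exceed the
#'   thresholds everywhere.
#' @param cohort `"control"` or `"patient"`.
#' @param ceilings Per-frequency maximum audiometer output in dB HL.
#' @return An `audiometric_table` (data frame).
#' @export
audiometric_table <- function(frequency, hearing_threshold, ldl,
                              cohort = c("control", "patient"),
                              ceilings = default_ceilings(frequency)) {
  cohort <- match.arg(cohort)
  if (!all(frequency %in% CLINICAL_FREQUENCIES))
    stop("frequencies must be drawn from the clinical set: ",
         paste(CLINICAL_FREQUENCIES, collapse = ", "), " Hz")
  if (any(ldl <= hearing_threshold))
    stop("LDL must exceed the hearing threshold at every frequency")
  out <- data.frame(frequency = frequency,
                    hearing_threshold = hearing_threshold,
                    ldl = ldl, ceiling = ceilings)
  attr(out, "cohort") <- cohort
  class(out) <- c("audiometric_table", "data.frame")
  out
}

#' Fixture generator specification
#'
#' @param control_ldl_shape Named numeric: control LDL in dB HL per
#'   frequency (names = Hz). Default: flat 100 dB HL over 250-8000 Hz.
#' @param control_ldl_frequencies Frequencies at which the control table
#'   reports LDLs (default 500-4000 Hz, the subset typically measured in
#'   controls).
#' @param patient_shift LDL shift of the patient cohort in dB
#'   (default -20).
#' @param jitter_sd Per-subject jitter standard deviation in dB
#'   (default 0: the table equals the shape exactly).
#' @param n_subjects Number of simulated subjects averaged (default 13).
#' @param seed Seed for the jitter.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(control_ldl_shape = NULL,
                         control_ldl_frequencies = c(500, 1000, 2000, 4000),
                         patient_shift = -20, jitter_sd = 0,
                         n_subjects = 13, seed = 1L) {
  if (is.null(control_ldl_shape)) {
    f <- CLINICAL_FREQUENCIES[CLINICAL_FREQUENCIES >= 250]
    control_ldl_shape <- stats::setNames(rep(100, length(f)), f)
  }
  structure(list(control_ldl_shape = control_ldl_shape,
                 control_ldl_frequencies = control_ldl_frequencies,
                 patient_shift = patient_shift, jitter_sd = jitter_sd,
                 n_subjects = n_subjects, seed = as.integer(seed)),
            class = "fixture_spec")
}

shape_at <- function(spec, frequency) {
  f <- as.numeric(names(spec$control_ldl_shape))
  stats::approx(f, spec$control_ldl_shape, xout = frequency, rule = 2)$y
}

jitter_means <- function(values, spec, seed_offset) {
  if (spec$jitter_sd == 0) return(values)
  with_seed(spec$seed + seed_offset, {
    vapply(values, function(v)
      mean(v + stats::rnorm(spec$n_subjects, 0, spec$jitter_sd)), 0)
  })
}

#' Generate a control audiometric table
#'
#' Normal-hearing controls: thresholds at 0 dB HL, LDLs following the
#' spec's shape (group mean over `n_subjects` jittered subjects when
#' `jitter_sd > 0`).
#'
#' @param spec A [fixture_spec()].
#' @return An `audiometric_table` with cohort `"control"`.
#' @export
make_control_table <- function(spec = fixture_spec()) {
  f <- spec$control_ldl_frequencies
  ldl <- jitter_means(shape_at(spec, f), spec, 0L)
  audiometric_table(f, hearing_threshold = rep(0, length(f)), ldl = ldl,
                    cohort = "control")
}

#' Generate a hyperacusis-patient audiometric table
#'
#' Patient LDLs equal the control LDL shape plus `patient_shift` (default
#' -20 dB) at every frequency; thresholds remain normal.
#'
#' @param spec A [fixture_spec()].
#' @param control Control table (used to verify the shift invariant at
#'   shared frequencies).
#' @param frequencies Frequencies for the patient table (default: the full
#'   clinical set).
#' @return An `audiometric_table` with cohort `"patient"`.
#' @export
make_patient_table <- function(spec = fixture_spec(),
                               control = make_control_table(spec),
                               frequencies = CLINICAL_FREQUENCIES) {
  ldl <- shape_at(spec, frequencies) + spec$patient_shift
  ldl <- jitter_means(ldl, spec, 1L)
  ht <- rep(0, length(frequencies))
  if (any(ldl <= ht))
    stop("patient shift drives LDL at or below the hearing threshold")
  audiometric_table(frequencies, hearing_threshold = ht, ldl = ldl,
                    cohort = "patient")
}

#' Write an audiometric table to CSV
#'
#' Columns: `cohort, frequency_hz, ht_db_hl, ldl_db_hl, ceiling_db_hl`.
#'
#' @param table An `audiometric_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_audiometric_csv <- function(table, path) {
  utils::write.csv(
    data.frame(cohort = attr(table, "cohort"),
               frequency_hz = table$frequency,
               ht_db_hl = table$hearing_threshold,
               ldl_db_hl = table$ldl,
               ceiling_db_hl = table$ceiling),
    path, row.names = FALSE)
  invisible(path)
}

#' Read an audiometric table from CSV
#' @param path CSV written by [write_audiometric_csv()].
#' @return An `audiometric_table`.
#' @export
read_audiometric_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("cohort", "frequency_hz", "ht_db_hl", "ldl_db_hl")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("malformed audiometric CSV: missing column(s) ",
         paste(missing, collapse = ", "))
  bad <- which(!is.finite(df$ldl_db_hl) | !is.finite(df$ht_db_hl))
  if (length(bad) > 0)
    stop("malformed audiometric CSV: non-numeric values in row ", bad[1])
  ceil <- if ("ceiling_db_hl" %in% names(df)) df$ceiling_db_hl
          else default_ceilings(df$frequency_hz)
  audiometric_table(df$frequency_hz, df$ht_db_hl, df$ldl_db_hl,
                    cohort = df$cohort[1], ceilings = ceil)
}
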