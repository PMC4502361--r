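# Human dual-resonance non-linear (DRNL) filterbank parameters.
# All per-channel coefficients are generated from log-linear regressions on
# the characteristic frequency: log10(param) = p0 + m * log10(cf).
# The linear-path gain uses log10(g) = p0 - g0 * log10(cf); g0 = 0.48 (the
# sign convention is chosen so that the gain decreases with cf, which is
# required for the non-linear path to dominate at low levels).
# stapes_scale converts the outer/middle-ear output (Pa) to stapes velocity
# (m/s); its value places the on-CF broken-stick knee of the 1-kHz channel
# near 35 dB SPL, the physiological onset of basilar-membrane compression.
version: 1
stapes_scale: 3.5e-03
# The three parallel bandpass branches are realised as zero-phase filters
# with Butterworth magnitude responses; order_low / order_high set the edge
# orders (asymmetric so that the branches stay flat inside their own bands
# without polluting each other, while the below-band skirt of the lowest
# branch keeps the shallow roll-off that forms the low-frequency pathway).
outer_middle_ear:
  filter_family: butterworth
  bands:
  - {low_cut: 1900.0, high_cut: 4200.0, gain_db: -2.0, order_low: 2, order_high: 12}
  - {low_cut: 4500.0, high_cut: 6300.0, gain_db: -3.0, order_low: 8, order_high: 12}
  - {low_cut: 8000.0, high_cut: 12000.0, gain_db: -19.0, order_low: 6, order_high: 4}
linear:
  n_gammatone: 2
  n_lowpass: 4
  lowpass_order: 2
  cf: {p0: -0.06762, m: 1.01679}
  bw: {p0: 0.03728, m: 0.78563}
  lp_cutoff: {p0: -0.06762, m: 1.01679}
  gain_p0: 4.20405
  g0: 0.48
nonlinear:
  n_gammatone: 3
  n_lowpass: 3
  lowpass_order: 2
  cf: {p0: -0.05252, m: 1.0165}
  bw: {p0: -0.03193, m: 0.77426}
  lp_cutoff: {p0: -0.05252, m: 1.0165}
  a: {p0: 1.40298, m: 0.81916}
  b: {p0: 1.61912, m: -0.81867}
  c: {p0: -0.60206, m: 0.0}
validity_range_hz: [100.0, 10000.0]
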