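# Default analysis configuration: the ten studied SBRT fraction schemes,
# linear-quadratic alpha/beta ratios and the published model parameters.
# Any field may be overridden; omitted sections fall back to package
# defaults. The Fenwick lung-NTCP model has no published defaults here --
# uncomment and fill the section to enable it.
schemes:
  - {n_fractions: 1, dose_per_fraction: 25}
  - {n_fractions: 1, dose_per_fraction: 30}
  - {n_fractions: 1, dose_per_fraction: 34}
  - {n_fractions: 3, dose_per_fraction: 15}
  - {n_fractions: 3, dose_per_fraction: 18}
  - {n_fractions: 3, dose_per_fraction: 20}
  - {n_fractions: 4, dose_per_fraction: 12}
  - {n_fractions: 5, dose_per_fraction: 12}
  - {n_fractions: 6, dose_per_fraction: 10}
  - {n_fractions: 10, dose_per_fraction: 7}
alpha_beta:
  tumor: 10
  lung: 1.3
  chest_wall: 3
tcp_models:
  martel: {d50: 84.5, gamma: 1.5}
  fenwick_tcp: {d50: 84.6, m: 0.329, c: 9.58, v_ref: 4.9}
  webb_nahum: {alpha_mean: 0.30, alpha_sd: 0.11, clonogen_density: 1.0e+8}
  eud: {tcd50: 51.24, gamma50: 0.83, alpha: 0.30}
  nitin: {c: 10, tcd50: 0, k: 31}
toxicity_models:
  lkb: {n_volume: 1.00, m: 0.45, td50: 26.8}
  # fenwick_ntcp: {d50: <Gy>, m: <slope>}
  meud: {exponent_alpha: 5, volume_cap: 100}
decision_rule:
  reference_scheme: 4x12
  ntcp_margin: 0.03
  meud_margin: 0.35
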