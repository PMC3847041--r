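# Genotype fixture registry: published summary values for each N-cadherin
# construct, used as ground-truth parameters of the synthetic generators for
# closed-loop validation. Quantities marked "nominal" are not published and
# were fixed once as realistic values (see the methods vignette).
#
# Units: fret ratios dimensionless fractions; rates junctions/min; taus in
# minutes (disassembly) or hours (spheroid); roundness dimensionless.
genotypes:
  WT:
    bleach_fret: {ratio: 0.199, n_obs: 35}
    ratiometric: {drop_fraction: 0.104, n_obs: 8}       # 100% -> 89.6%
    assembly: {rate: 0.203, presence_fraction: 0.82, n_fov: 3}
    lifetime: {presence_fraction: 0.82, n_junctions: 15}
    disassembly: {tau: 2.63, lag: 0, plateau_fraction: 0.9}
    spheroid:
      plateau_48h: 0.68
      roundness_3h: 0.53
      roundness_20h: 0.62
      roundness_start: 0.15    # nominal
      tau_fast: 1.5            # h, nominal
      tau_slow: 10.0           # h, nominal
  W2A:
    bleach_fret: {ratio: 0.294, n_obs: 32}
    ratiometric: {drop_fraction: 0.254, n_obs: 8}       # 100% -> 74.6%
    assembly: {rate: 0.053, presence_fraction: 0.39, n_fov: 3}
    lifetime: {presence_fraction: 0.39, n_junctions: 17}
    disassembly: {tau: 3.0, lag: 0, plateau_fraction: 0.75}  # tau nominal
    spheroid:
      plateau_48h: 0.27
      roundness_3h: 0.13
      roundness_20h: 0.32
      roundness_start: 0.12    # nominal
      tau_fast: 2.0            # h, nominal
      tau_slow: 10.0           # h, nominal
  R14E:
    bleach_fret: {ratio: 0.140, n_obs: 29}
    ratiometric: {drop_fraction: 0.004, n_obs: 9}       # 99.2% -> 98.8%
    assembly: {rate: 0.095, presence_fraction: 0.75, n_fov: 3}
    lifetime: {presence_fraction: 0.75, n_junctions: 12}
    disassembly: {tau: 7.28, lag: 10, plateau_fraction: 0.85}
    spheroid:
      plateau_48h: 0.68
      roundness_3h: 0.24
      roundness_20h: 0.61
      roundness_start: 0.12    # nominal
      tau_fast: 3.0            # h, nominal
      tau_slow: 12.0           # h, nominal
  V81D_V174D:
    bleach_fret: {ratio: 0.224, n_obs: 33}
    ratiometric: {drop_fraction: 0.195, n_obs: 7}       # 100% -> 80.5%
    assembly: {rate: 0.006, presence_fraction: 0.06, n_fov: 3}
    lifetime: {presence_fraction: 0.06, n_junctions: 15}
    disassembly: {tau: 3.54, lag: 0, plateau_fraction: 0.9}
    spheroid:
      plateau_48h: 0.57
      roundness_3h: 0.23
      roundness_20h: 0.44
      roundness_start: 0.12    # nominal
      tau_fast: 3.0            # h, nominal
      tau_slow: 14.0           # h, nominal
  EC5:
    bleach_fret: {ratio: 0.038, n_obs: 8}               # inter-fluorophore control
# WT spheroid roundness at 20 h versus external calcium, and the logistic
# calibrated to it (used when SpheroidParams are built from ca_ext)
ca_dose:
  ca_mM: [0.0, 0.4, 0.8, 1.3, 2.1]
  roundness_20h: [0.30, 0.51, 0.60, 0.61, 0.63]
  logistic: {lo: 0.0118, hi: 0.6233, c50: 0.0287, scale: 0.2495}
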