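# Demonstration config exercising every stage at desk scale: synthetic data
# are generated from the bundled Dre2 reference parameters and refitted.
seed: 1
stages:
  - name: tables
    rows:
      - construct: ntd
      - construct: fl-apo
      - construct: fl-holo
  - name: decay
    generator:
      construct: ntd
    irf: {peak: 2, fwhm: 0.5, n_channels: 2048, channel_width: 0.02}
    total_counts: 1.0e+6
    n_components: 3
  - name: anisotropy
    generator:
      construct: ntd
    irf: {peak: 2, fwhm: 0.5, n_channels: 2048, channel_width: 0.02}
    total_counts: 1.0e+6
    n_rot: 3
    g_factor: 1
  - name: epr_saturation
    generator:
      scale_C: 1
      p_half: 2.5
      b: 1
      powers: {from: 2.0e-4, to: 200, per_decade: 4}
      noise_fraction: 0.02
  - name: epr_quant
    sample: {center_field: 331.3, linewidth: 2.0, area: 4, shape: gaussian}
    standard: {center_field: 331.3, linewidth: 3.0, area: 15, shape: gaussian}
    standard_conc: 15
    protein_conc: 10
  - name: hydro
    mass: 15000
    vbar: 0.753
    f_over_f0: 1.1
    hydration: 0.4
    convention: radius-scale
  - name: melt
    generator:
      midpoint: 62
      dH: 400
      folded: [-20, 0]
      unfolded: [-2, 0]
      from: 10
      to: 80
      by: 1
      noise_sd: 0.36
    baselines: flat
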