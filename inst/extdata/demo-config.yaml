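# Demo configuration for the command-line pipeline: a small virtual world
# with two fast model families. All keys not listed here take defaults.
seed: 7
world:
  n_rows: 14
  n_cols: 14
  n_countries: 12
  n_species: 2
prep:
  n_pseudo: 100
selection:
  run: false
ensemble:
  families: ["glm_poly", "gam_spline"]
  min_projections: 5
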