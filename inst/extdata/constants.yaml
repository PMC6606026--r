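# Reported constants used by the reproduction pipeline.
genome:
  mappable_genome_bp: 2.7e+09      # mappable (non-repetitive) human genome
  hela_genome_bp: 7.9e+09          # HeLa genome size
  n_chromosomes: 64                # average HeLa karyotype
sites:                             # peak counts in the mappable genome (G1)
  cohesin_generic: 40000           # the rounded per-target count used for scaling
  ctcf: 41000
  smc3: 37000
  stag1: 35000
  stag2: 47000
copies:
  ctcf_nuclear_g1: 180000          # rounded nuclear CTCF copies in G1
  prometaphase_chromatin_cohesin: 14000
kinetics:
  residence_dynamic_g1_min: 13.7
  residence_dynamic_g2_min: 10.0
  residence_stable_g2_hr: 8.6
loops:
  median_tad_kb: 185
  cohesin_spacing_loop_kb: 100
equilibrium:
  bound_fraction_g1: 0.635
  stable_fraction_g2: 0.367
  observed_bound_fraction_g2: 0.728
srm:
  spike_fmol_soluble: [2.5, 5]
  spike_fmol_chromatin: [10, 15]
  n_cells_chromatin: 62500
  n_cells_chromatin_sd: 3100
  acetone_loss: 0.17
qc:
  r2_min: 0.92
  chisq_max: 1.2
  tukey_k: 3
  cpm_cap: 10
volumes:
  v_ratio_interphase: 3.04
  v_ratio_prometaphase: 5.72
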