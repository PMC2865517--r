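# Flat model configuration for the episodic (seizure-like) regime:
# reduced glial buffering and raised reservoir coupling at physiological
# bath potassium.  Load with load_config().
G_glia:
  value: 40.0
  unit: mM/s
eps:
  value: 2.0
  unit: 1/s
K_bath:
  value: 3.0
  unit: mM
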