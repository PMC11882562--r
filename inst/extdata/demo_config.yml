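# Demo generator configuration: the default 10-site x 3-season survey
# layout with two factor-linked genes. Values are percent/log2 slopes
# per standardized factor unit.
seed: 2021
n_sites: 10
seasons: [spring, summer, autumn]
expression_links:
  CsSCPL: {rainfall: 1.0, temp_max: 0.6}
  CsCHS1: {temp_min: -0.8, irradiance: 0.5}
  CsANR: {temp_avg: 0.7}
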