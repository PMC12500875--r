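variables:
  IC_org:
    role: independent
    description: influent organic carbon concentration
    unit: g/m^3
    dims:
      mass: 1.0
      length: -3.0
    convert:
      factor: 1.0
      offset: 0.0
  C_fit:
    role: independent
    description: filter bed diameter
    unit: m
    dims:
      length: 1.0
    convert:
      factor: 0.001
      offset: 0.0
  A:
    role: independent
    description: filter age since start of operation
    unit: s
    dims:
      time: 1.0
    convert:
      factor: 86400.0
      offset: 0.0
  T:
    role: independent
    description: water temperature at the sample location
    unit: K
    dims:
      temperature: 1.0
    convert:
      factor: 1.0
      offset: 273.15
  Pz:
    role: independent
    description: characteristic pore size of the filter medium
    unit: m
    dims:
      length: 1.0
    convert:
      factor: 0.001
      offset: 0.0
  Bt:
    role: independent
    description: empty bed contact time
    unit: s
    dims:
      time: 1.0
    convert:
      factor: 3600.0
      offset: 0.0
  P:
    role: independent
    description: mean GAC particle diameter
    unit: m
    dims:
      length: 1.0
    convert:
      factor: 0.001
      offset: 0.0
  t0:
    role: independent
    description: ambient air temperature
    unit: K
    dims:
      temperature: 1.0
    convert:
      factor: 1.0
      offset: 273.15
  EC_org:
    role: dependent
    description: effluent organic carbon concentration
    unit: g/m^3
    dims:
      mass: 1.0
      length: -3.0
    convert:
      factor: 1.0
      offset: 0.0
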