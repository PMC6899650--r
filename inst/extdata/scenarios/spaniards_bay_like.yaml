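surface_name: spaniards_bay_like
window:
  xrange:
  - 0.0
  - 5.86
  yrange:
  - 0.0
  - 2.8
taxa:
- taxon: beothukis_like
  process: HP
  target_n: 18.0
  params:
    covariate: gradient_x
    b: 0.5
  size_distribution:
    meanlog: -2.5257286
    sdlog: 0.4
- taxon: trepassia_like
  process: ITC
  target_n: 33.0
  params:
    sigma: 0.1
    rho: 0.6
    surface:
      covariate: gradient_x
      b: 0.5
  size_distribution:
    meanlog: -2.5257286
    sdlog: 0.4
- taxon: avalofractus_like
  process: CSR
  target_n: 18.0
  size_distribution:
    meanlog: -3.2188758
    sdlog: 0.4
strain:
  ratio: 1.35
  orientation: 0.5235988
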