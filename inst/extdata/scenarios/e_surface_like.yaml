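surface_name: e_surface_like
window:
  xrange:
  - 0.0
  - 10.7
  yrange:
  - 0.0
  - 8.0
taxa:
- taxon: fractofusus_like
  process: TC
  target_n: 1137.0
  params:
    sigma: 0.12
    rho: 1.1256534
  size_distribution:
    meanlog: -2.8134107
    sdlog: 0.4
- taxon: feather_duster_like
  process: TC
  target_n: 272.0
  params:
    sigma: 0.15
    rho: 0.5674232
  size_distribution:
    meanlog: -2.9957323
    sdlog: 0.4
- taxon: charniodiscus_like
  process: DTC
  target_n: 326.0
  params:
    sigma: 0.5
    rho: 0.35
    small_sigma: 0.08
    small_mu: 2.1
  size_distribution:
    meanlog: -2.9957323
    sdlog: 0.4
- taxon: beothukis_like
  process: HP
  target_n: 76.0
  params:
    covariate: gradient_x
    b: 0.35
  size_distribution:
    meanlog: -2.9957323
    sdlog: 0.4
- taxon: thectardis_like
  process: CSR
  target_n: 39.0
  size_distribution:
    meanlog: -2.9957323
    sdlog: 0.4
- taxon: bradgatia_like
  process: CSR
  target_n: 34.0
  size_distribution:
    meanlog: -2.8134107
    sdlog: 0.4
- taxon: ivesheadiomorphs
  process: CSR
  target_n: 700.0
  size_distribution:
    meanlog: -2.5257286
    sdlog: 0.4
  group_class: taphomorph
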