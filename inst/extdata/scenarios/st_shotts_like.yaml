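surface_name: st_shotts_like
window:
  xrange:
  - 0.0
  - 10.2
  yrange:
  - 0.0
  - 5.0
taxa:
- taxon: aspidella_like
  process: TC
  target_n: 170.0
  params:
    sigma: 0.3
    rho: 0.3623188
  size_distribution:
    meanlog: -3.5065579
    sdlog: 0.4
- taxon: charnia_like
  process: TC
  target_n: 54.0
  params:
    sigma: 0.35
    rho: 0.0962567
  size_distribution:
    meanlog: -2.8134107
    sdlog: 0.4
- taxon: holdfast_discs
  process: CSR
  target_n: 150.0
  size_distribution:
    meanlog: -3.5065579
    sdlog: 0.4
  group_class: bin_group
- taxon: ivesheadiomorphs
  process: CSR
  target_n: 100.0
  size_distribution:
    meanlog: -2.5257286
    sdlog: 0.4
  group_class: taphomorph
erosion:
  kind: gradient_y
  b: -0.3
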