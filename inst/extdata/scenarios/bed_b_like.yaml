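surface_name: bed_b_like
window:
  xrange:
  - 0.0
  - 14.4
  yrange:
  - 0.0
  - 8.0
taxa:
- taxon: charniodiscus_like
  process: TC
  target_n: 48.0
  params:
    sigma: 0.25
    rho: 0.1436782
  size_distribution:
    meanlog: -3.2188758
    sdlog: 0.4
- taxon: primocandelabrum_like
  process: TC
  target_n: 106.0
  params:
    sigma: 0.3
    rho: 0.0427972
  size_distribution:
    meanlog: -2.9957323
    sdlog: 0.4
- taxon: charnia_like
  process: TC
  target_n: 69.0
  params:
    sigma: 0.3
    rho: 0.0499132
  size_distribution:
    meanlog: -2.8134107
    sdlog: 0.4
- taxon: holdfast_discs
  process: CSR
  target_n: 250.0
  size_distribution:
    meanlog: -3.5065579
    sdlog: 0.4
  group_class: bin_group
- taxon: ivesheadiomorphs
  process: CSR
  target_n: 200.0
  size_distribution:
    meanlog: -2.5257286
    sdlog: 0.4
  group_class: taphomorph
- taxon: hiemalora_like
  process: CSR
  target_n: 80.0
  size_distribution:
    meanlog: -3.5065579
    sdlog: 0.4
  group_class: organ_taxon
erosion:
  kind: gradient_x
  b: -0.15
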