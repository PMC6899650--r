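surface_name: bristy_cove_like
window:
  xrange:
  - 0.0
  - 0.9
  yrange:
  - 0.0
  - 0.9
taxa:
- taxon: fractofusus_like
  process: CSR
  target_n: 76.0
  size_distribution:
    meanlog: -4.6051702
    sdlog: 0.3
- taxon: holdfast_discs
  process: CSR
  target_n: 30.0
  size_distribution:
    meanlog: -4.8283137
    sdlog: 0.3
  group_class: bin_group
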