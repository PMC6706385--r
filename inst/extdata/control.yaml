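genotype: WT
temperature: 36.0
pump: 30.0
resurgent_fraction: 0.27
membrane:
  cn: 1.5
  ci: 120.0
  gna: 300.0
  gnap: 1.5
  gksn: 25.0
  gkfn: 80.0
  gln: 3.0
  gkfi: 60.0
  gh: 10.0
  gli: 6.0
  gbb: 20.0
  ena: 50.0
  ek: -95.0
  eh: -45.0
  elk: -85.0
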