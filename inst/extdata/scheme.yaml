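states:
- C1
- C2
- C3
- C4
- O1
- IC1
- IC2
- IC3
- IC4
- I1
- O2
- I2
conducting:
- O1
- O2
transitions:
- from: C1
  to: C2
  rate: alpha
  mult: 3.0
- from: C2
  to: C1
  rate: beta
  mult: 1.0
- from: IC1
  to: IC2
  rate: alpha
  mult: 3.0
- from: IC2
  to: IC1
  rate: beta
  mult: 1.0
- from: C2
  to: C3
  rate: alpha
  mult: 2.0
- from: C3
  to: C2
  rate: beta
  mult: 2.0
- from: IC2
  to: IC3
  rate: alpha
  mult: 2.0
- from: IC3
  to: IC2
  rate: beta
  mult: 2.0
- from: C3
  to: C4
  rate: alpha
  mult: 1.0
- from: C4
  to: C3
  rate: beta
  mult: 3.0
- from: IC3
  to: IC4
  rate: alpha
  mult: 1.0
- from: IC4
  to: IC3
  rate: beta
  mult: 3.0
- from: C4
  to: O1
  rate: gamma
  mult: 1.0
- from: O1
  to: C4
  rate: delta
  mult: 1.0
- from: IC4
  to: I1
  rate: gamma
  mult: 1.0
- from: I1
  to: IC4
  rate: delta
  mult: 1.0
- from: C1
  to: IC1
  rate: c_on
  mult: 1.0
- from: IC1
  to: C1
  rate: c_off
  mult: 1.0
- from: C2
  to: IC2
  rate: c_on
  mult: 1.0
- from: IC2
  to: C2
  rate: c_off
  mult: 1.0
- from: C3
  to: IC3
  rate: c_on
  mult: 1.0
- from: IC3
  to: C3
  rate: c_off
  mult: 1.0
- from: C4
  to: IC4
  rate: c_on
  mult: 1.0
- from: IC4
  to: C4
  rate: c_off
  mult: 1.0
- from: O1
  to: I1
  rate: o_on
  mult: 1.0
- from: I1
  to: O1
  rate: o_off
  mult: 1.0
- from: O1
  to: O2
  rate: o1o2
  mult: 1.0
- from: O2
  to: O1
  rate: o2o1
  mult: 1.0
- from: O2
  to: I2
  rate: o2i2
  mult: 1.0
- from: I2
  to: O2
  rate: i2o2
  mult: 1.0
- from: I1
  to: I2
  rate: i1i2
  mult: 1.0
- from: I2
  to: I1
  rate: i2i1
  mult: 1.0
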