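# SYNTHETIC demography fixture: a generic bottleneck-plus-growth history for
# demonstrating demographic effects on architecture. These values are fixture
# choices, NOT an inferred human history.
epochs:
  - gens: 40000
    N: 10000
  - gens: 1500
    N: 2000
  - gens: 200
    N_start: 2000
    N_end: 100000
    mode: exp
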