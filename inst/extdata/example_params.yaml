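# Example model configuration: a height-like trait in the pleiotropic limit.
# v_s = 2 w^2/(n N) = 4.05e-4 (fractions of V_P); theta = 4Nu = 4e-4 per site.
n: 10
w: 4.5
N: 10000
u: 1.0e-8
L: 5000000
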