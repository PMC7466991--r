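# example scenario: germline conversion, costs on zygote survival,
# recessive (h = 0), universal brake released at drive frequency 0.5
# eradication standardisation d_DD/(omega_DD beta_DD^2) = 1.1, N* = 10000
c_D: 0.95
c_B: 0.95
h: 0.0
timing: germline
targeted_trait: omega
brake_kind: universal
omega00: 1.0
d00: 0.1
beta00: 1.0
drive_ratio: 1.1
restoration: 0.95
K: 11111.111111111111313
f_I: 0.5
N0B: 100.0
drive_intro: 100.0
dt: 0.005
thr: 0.01
tmax: 2500.0
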