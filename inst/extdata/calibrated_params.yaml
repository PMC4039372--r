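ka_wcc: 0.25
ka_vvd: 0.503
kd_wcc: 0.005
kd_vvd: 0.0211
kdim_wcc: 8.550000000000001
kundim_wcc: 0.289
kpad_wcc: 0.01
kdim_vvd: 3.68
kundim_vvd: 0.0316
kpad_vvd: 0.002
l1: 25.600000000000001
lm1: 0.118
l5: 0.15
bas_wc1: 0.003
vmax_wc1: 0.0058
K_wc1: 0.071
vmax_frq: 0.1
K_frq: 0.071
vc_frq: 0.02
K_cbox: 0.5
vmax_vvd: 2.13
K_vvd: 0.303
bas_vvd: 6.0e-05
hill_lre: 2.0
hill_cbox: 2.0
dm_wc1: 0.03
dm_frq: 0.05
dm_vvd: 0.109
ktl_wc1: 0.0511
ktl_frq: 0.02
ktl_vvd: 0.949
dg_wcc_d: 0.00205
dg_wcc_a: 0.0108
dg_wcc_aa: 0.0108
dg_wcc_p: 0.0015
dg_het: 0.0003
dg_vvd_d: 0.016
dg_vvd_a: 0.0045
dg_vvd_aa: 0.0045
dg_frq_c: 0.004
dg_frq_n: 0.002
dg_frq_p: 0.02
kin_frq: 0.002
kph: 0.06
K_ph: 20.0
kdp: 0.002
K_dp: 50.0
kpf: 0.002
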