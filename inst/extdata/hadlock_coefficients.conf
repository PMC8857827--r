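# Hadlock-type log10 EFW regression coefficients (cm in, grams out):
# log10(EFW) = b0 + b_bpd*BPD + b_hc*HC + b_ac*AC + b_fl*FL + b_acfl*AC*FL
# Default: the widely published HC/AC/FL model. Coefficients are config
# data so a deployment can substitute another published table.
b0 = 1.326
b_bpd = 0
b_hc = 0.0107
b_ac = 0.0438
b_fl = 0.158
b_acfl = -0.00326
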