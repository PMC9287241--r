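# Example configuration: default parametrisation with a TBN network and a
# 1-s stimulus onset interval. Any omitted parameter keeps its default.
variant: TBN
soi: 1.0
n_stimuli: 111
tau_rec: 5
w_ee_ff: 0.5
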