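# Synthetic default gating-parameter set (not fitted to any recording).
# Units: A in 1/mV, V0/Ro/Rc in mV, K and P dimensionless, tau in time units.
A: 0.04
P: 1
K: 0.01
V0: 25
Ro: 100
Rc: 100
tau: 1
deep.A: 0.02
deep.P: 1
deep.K: 0.01
deep.V0: 40
g_deep_policy: closed
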