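# Example run configuration: MiaPaca-2 under the 30 nM palbociclib +
# 12 h-delayed 30 nM gemcitabine cyclotherapy protocol.
profile: miapaca2
use_normal_counterpart: no
egf_conc: 0
horizon: 72
n0: 1000
drugs:
  - palbociclib
  - gemcitabine
schedule:
  - drug: palbociclib
    concentration: 30
    t_start: 0
    t_end: 48
  - drug: gemcitabine
    concentration: 30
    t_start: 12
    t_end: 36
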