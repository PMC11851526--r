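method,setting,f1,accuracy
lstm,predicted8,81.50,91.16
lstm,ground8,81.59,91.03
lstm,groundAll,82.63,91.74
transformer,predicted8,82.10,90.81
transformer,ground8,82.36,90.89
transformer,groundAll,84.53,92.11
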