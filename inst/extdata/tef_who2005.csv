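chemical,tef
PCB118,0.00003
PCB126,0.100
PCB169,0.030
D03,0.100
D05,0.010
D07,0.0003
F03,0.300
F04,0.100
F08,0.010
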