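field	value
name	C5(bpyr)2
dication_formula	C21H44N2
dication_charge	2
neutral_loss_formula	C8H17N
fragment_formula	C13H26N
counterion_formula	F
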