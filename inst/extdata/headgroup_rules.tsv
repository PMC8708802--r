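lipid_class	headgroup_anion_formula	secondary_neutral_loss
PA	H2O4P	
PE	C2H7NO4P	C2H5N
PI	C6H12O9P	
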