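compound,phase,e_total_au,dipole_D,e_homo_au,e_lumo_au,suspect
2H,gas,,,-0.23738,-0.11034,FALSE
2H,aqueous,,,-0.23132,-0.10799,FALSE
6H,gas,,,-0.24851,-0.12131,FALSE
6H,aqueous,,,-0.23470,-0.11624,FALSE
7H,gas,,,-0.22399,-0.10882,FALSE
7H,aqueous,,,-0.22796,-0.10734,FALSE
9H,aqueous,,,-0.22796,-0.10734,TRUE
9H,aqueous,,,-0.20005,-0.10646,FALSE
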