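Shock
Cardiogenic shock
Septic shock
Anaphylactic shock
Hypovolemic shock
Distributive shock
Circulatory collapse
Neurogenic shock
Obstructive shock
Toxic shock syndrome
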