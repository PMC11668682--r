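name	start	end	label
SYNTRAJ01	0	8	CDR3
SYNTRAJ02	0	8	CDR3
SYNTRAJ03	0	8	CDR3
SYNTRAJ04	0	8	CDR3
SYNTRAJ05	0	8	CDR3
SYNTRAJ06	0	8	CDR3
SYNTRAJ07	0	8	CDR3
SYNTRAJ08	0	8	CDR3
SYNTRAJ09	0	8	CDR3
SYNTRAJ10	0	8	CDR3
SYNTRAJ11	0	8	CDR3
SYNTRAJ12	0	8	CDR3
SYNTRAJ13	0	8	CDR3
SYNTRAJ14	0	8	CDR3
SYNTRAJ15	0	8	CDR3
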