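effect_type,duration_class,factor
LC50,acute,30
LC50,chronic,10
LC50,any,30
EC50,acute,30
EC50,chronic,10
EC50,any,30
NOEC,acute,3
NOEC,chronic,1
NOEC,any,3
LOEC,acute,10
LOEC,chronic,1
LOEC,any,10
other,any,30
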