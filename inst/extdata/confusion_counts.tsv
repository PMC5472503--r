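actual	predicted_control	predicted_case
control	41	1
case	3	39
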