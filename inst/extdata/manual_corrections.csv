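generic_name,panel
moxifloxacin,herg
probenecid,other
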