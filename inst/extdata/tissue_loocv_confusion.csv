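true,Responders,Non-responders
Responders,31,14
Non-responders,3,42
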