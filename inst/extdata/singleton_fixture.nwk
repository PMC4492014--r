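((otuA:1,otuB:2):1,(otuC:1,otuD:3):2);
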