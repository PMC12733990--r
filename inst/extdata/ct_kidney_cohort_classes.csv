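class,training,validation,test
normal,1014,217,217
cyst,754,162,162
tumor,446,96,96
stone,275,59,59
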