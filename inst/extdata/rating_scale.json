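{"name":"rating","supports_reciprocals":false,"terms":{"P":[0,2.5,5],"F":[2.5,5,7.5],"G":[5,7.5,10],"VG":[7,10,10]}}
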