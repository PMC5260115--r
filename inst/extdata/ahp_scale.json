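{"name":"ahp","supports_reciprocals":true,"terms":{"E":[1,1,1],"SI":[1,1,3],"FI":[1,3,5],"HI":[3,5,7],"VI":[5,7,9],"EI":[7,9,9]}}
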