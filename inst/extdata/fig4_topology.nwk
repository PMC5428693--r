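((((Gorilla:9,(Homo:8,(P_paniscus:2,P_troglodytes:2):6):1):7,Pongo:16):4,Hylobatids:20):5,Outgroup:25);
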