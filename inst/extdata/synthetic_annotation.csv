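id,group,functional_class,family
CAP01,Viruses,viral icosahedral capsid,SynFamA
CAP02,Viruses,viral icosahedral capsid,SynFamB
ENZ01,Eukaryota,enzyme,
ACD01,Bacteria,,
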