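virus,family,genome_type,t_number,components,genome_segments,host_class,motor_packaged,q_max
SynVirus01,SynFamA,+ssRNA,3,CP:180,4500,eukaryotic,FALSE,18
SynVirus02,SynFamA,+ssRNA,3,CP:180,4100,eukaryotic,FALSE,16
SynVirus03,SynFamB,ssDNA,1,CP:60,2000,eukaryotic,FALSE,24
SynVirus04,SynFamB,ssDNA,1,CP:60,1800,eukaryotic,FALSE,21
SynVirus05,SynFamC,dsDNA,7,L1:360;L2:72,5000,eukaryotic,FALSE,16;12
SynVirus06,SynFamC,dsDNA,7,L1:360;L2:72,5300,eukaryotic,FALSE,17;13
SynVirus07,SynFamD,ssDNA,1,F:60;J:60;H:12,4400,bacteriophage,FALSE,2;12;10
SynVirus08,SynFamE,dsDNA,7,MCP:415,39900,bacteriophage,TRUE,3
SynVirus09,SynFamE,dsDNA,7,MCP:415,41000,bacteriophage,TRUE,4
SynVirus10,SynFamF,+ssRNA,3,CP:180,3600,eukaryotic,FALSE,15
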