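id,acronym,name,parent_id
997,root,root,
688,CTX,cerebral cortex,997
695,L23,"cortical layer 2/3",688
698,L5,"cortical layer 5",688
313,MB,midbrain,997
749,VTA,ventral tegmental area,313
381,SNr,"substantia nigra, reticular part",313
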