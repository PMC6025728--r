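gene	group	known_function	gcl_p3	gcl_consistent	brn3a_target_p3	brn3a_target_any	onset	peak	offset	sparse	brn3a_independent_transcripts	brn3a_regulation_gene_level
Foxp2	Transcriptional and translational regulators	TF	yes	no	no	yes	P0	P7	none	no	no	yes
Tshz2	Transcriptional and translational regulators	TF	yes	yes	yes	yes	P3	P7	none	no	no	yes
Rbfox1	Transcriptional and translational regulators	Splicing of neuronal genes	yes	no	no	no	P0	P14	none	no	yes	no
Eml1	Intracellular signaling and cytoskeleton-associated genes	Microtubule-binding protein	yes	no	no	no	P0	P7	none	no	yes	no
Hpca	Intracellular signaling and cytoskeleton-associated genes	Calcium sensor	yes	yes	no	yes	P0	P7-P14	none	no	yes	no
Plppr3	Intracellular signaling and cytoskeleton-associated genes	Neurite growth and regeneration	yes	yes	no	yes	P0	P0	none	no	no	no
Mapk10	Intracellular signaling and cytoskeleton-associated genes	Axonal growth and neuronal survival	yes	yes	no	yes	P0	P7-P14	none	yes	yes	no
Pip5kl1	Intracellular signaling and cytoskeleton-associated genes	Cell morphology and adhesion	no	no	no	no	P3	P7	none	no	no	no
Pak6	Intracellular signaling and cytoskeleton-associated genes	Signaling kinase	no	no	no	no	none	none	none	no	no	na
Ankrd13b	Vesicle-associated proteins	Caveolin-mediated endosomal traffick	yes	yes	no	no	P0	P7	none	no	no	no
Pick1	Vesicle-associated proteins	Glutamate receptor trafficking	yes	no	no	no	P0	none	none	no	yes	no
Snap91	Vesicle-associated proteins	Clathrin-mediated endocytosis	yes	yes	yes	yes	P0	P7-P14	none	yes	yes	no
Tusc5	Vesicle-associated proteins	Insulin-stimulated glucose transport	yes	yes	yes	yes	P3	P14	none	yes	no	yes
Elfn1	Synapse-associated proteins	Synaptic adhesion protein	yes	no	no	yes	P3	P7	none	yes	no	yes
Gabra1	Synapse-associated proteins	GABA receptor alpha1 subunit	no	no	no	yes	P3	none	none	yes	no	yes
Grm4	Synapse-associated proteins	Metabotropic glutamate receptor	yes	no	no	no	P0	P7	none	no	no	yes
Ntrk1	Synapse-associated proteins	Neurotrophin receptor	yes	no	no	no	P0	P14-P22	none	no	no	yes
Pnkd	Synapse-associated proteins	Synaptic vesicle release	no	yes	no	no	P0	P7-P14	none	yes	yes	no
Rims1	Synapse-associated proteins	Synaptic vesicle release & recycling	yes	yes	no	yes	P0	P0-P3	none	yes	no	no
Fam19a4	Secreted proteins	Unknown	no	no	no	no	P3	P3-P7	P7	no	no	yes
Nptx1	Secreted proteins	Trans-synaptic, excitatory synapse	yes	yes	no	yes	P0	P14	none	yes	no	yes
Nptx2	Secreted proteins	Trans-synaptic, excitatory synapse	yes	no	no	no	P3	P7-P14	none	yes	no	yes
Sez6l2	Secreted proteins	Synapse formation	yes	yes	no	yes	P3	P7	none	no	yes	no
Cdh4	Adhesion molecules and other transmembrane proteins	Cell adhesion molecule	yes	no	yes	yes	P0	none	none	yes	no	yes
Pcdh20	Adhesion molecules and other transmembrane proteins	Cell adhesion molecule	no	no	no	yes	P14	none	none	no	no	yes
Rtn4rl2	Adhesion molecules and other transmembrane proteins	Axon guidance molecule	yes	yes	no	yes	P0	none	P22	no	no	no
Tmem25	Adhesion molecules and other transmembrane proteins	Unknown	no	no	no	no	P0	P7-P14	none	no	no	no
Tmem91	Adhesion molecules and other transmembrane proteins	Unknown	no	no	no	yes	P0	P7-P14	none	no	yes	no
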