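antibiotic efflux
antibiotic inactivation
antibiotic target alteration
antibiotic target protection
antibiotic target replacement
beta-lactamase
extended-spectrum beta-lactamase
metallo-beta-lactamase
carbapenemase
penicillin-binding protein
aminoglycoside acetyltransferase
aminoglycoside phosphotransferase
aminoglycoside nucleotidyltransferase
chloramphenicol acetyltransferase
macrolide phosphotransferase
rifampin ADP-ribosyltransferase
tetracycline efflux pump
multidrug efflux pump
resistance-nodulation-division efflux
major facilitator superfamily transporter
ABC transporter
porin loss
outer membrane permeability
lipopolysaccharide modification
peptidoglycan biosynthesis
cell wall biogenesis
DNA gyrase
topoisomerase IV
fluoroquinolone resistance
quinolone resistance protein
dihydrofolate reductase
dihydropteroate synthase
sulfonamide resistance
trimethoprim resistance
vancomycin resistance
glycopeptide resistance gene cluster
D-alanine ligase
methicillin resistance
mecA
vanA
tetA
tetM
ermB
qnrS
blaTEM
blaSHV
blaCTX-M
blaNDM
blaKPC
aac(6')-Ib
aph(3')-IIIa
oqxAB
acrAB-tolC
mexAB-oprM
horizontal gene transfer
mobile genetic element
integron
plasmid-mediated resistance
efflux pump regulator
response to antibiotic
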