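target_uniprot,gene_symbol,pdb_code,known_ligand_name,known_mmgbvi,known_pki,icariin_mmgbvi,icariin_pki
Q13464,ROCK1,2ETK,Hydroxyfasudil,-21.03,8.10,-33.03,14.34
P00439,PAH,4PAH,Norepinephrine,-26.24,7.05,-44.04,7.90
Q9HAN9,NMNAT1,1GZU,Nicotinamide Mononucleotide,-27.30,12.54,-23.15,17.75
Q9BW91,NUDT9,1Q33,beta-d-Glucose,-24.64,10.70,-34.00,13.26
P50135,HNMT,2AOU,Amodiaquine,-26.05,6.91,-22.14,6.10
Q10588,BST1,1ISG,Adenosine-5'-diphosphate Monothiophosphate,-14.33,9.41,-24.31,10.99
P06737,PYGL,1FA9,Adenosine Monophosphate,-17.06,8.66,-27.18,9.79
P00750,PLAT,1PK2,Aminocaproic Acid,-19.90,9.71,-24.92,9.30
O76074,PDE5,2H42,Sildenafil,-36.25,9.67,-28.87,13.89
P04062,GBA,2F61,2-(Acetylamino)-2-deoxy-a-d-glucopyranose,-16.41,5.57,-21.80,11.17
P15291,B4GALT1,4EEG,N-Acetyl-d-glucosamine,-19.15,8.97,-34.21,10.75
P07737,PFN1,1CJF,7-Hydroxy-4-methyl-3-(2-hydroxy-ethyl)coumarin,-15.42,6.69,-27.05,8.67
P09012,SNRPA,1NU4,Malonic Acid,-22.16,6.52,-23.86,5.34
P84077,ARF1,1U81,"1,3-Propandiol",-37.77,4.64,-43.17,11.18
Q08209,PPP3CA,4F0Z,Myristic Acid,-15.56,4.64,-22.51,8.90
P13569,CFTR,2BBO,Ibuprofen,-8.23,6.00,-6.62,11.01
P02774,GC,1J78,Cholecalciferol,-10.99,5.05,-21.56,6.43
P11387,TOP1,1TL8,Irinotecan,-34.75,14.32,-20.04,17.80
P19883,FST,2B0U,d-Myo-inositol-hexasulphate,-9.54,7.03,-24.81,9.78
P27695,APEX1,4QHE,Lucanthone,-16.70,4.25,-17.73,4.56
P22303,AChE,1F8U,Mefloquine,-11.44,6.54,-34.86,7.97
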