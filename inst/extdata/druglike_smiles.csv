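compound_id,smiles
aspirin,CC(=O)Oc1ccccc1C(=O)O
caffeine,Cn1cnc2c1c(=O)n(C)c(=O)n2C
paracetamol,CC(=O)Nc1ccc(O)cc1
ibuprofen,CC(C)Cc1ccc(cc1)C(C)C(=O)O
naproxen,COc1ccc2cc(ccc2c1)C(C)C(=O)O
nicotine,CN1CCC[C@H]1c1cccnc1
benzocaine,CCOC(=O)c1ccc(N)cc1
salbutamol,CC(C)(C)NCC(O)c1ccc(O)c(CO)c1
atenolol,CC(C)NCC(O)COc1ccc(CC(N)=O)cc1
propranolol,CC(C)NCC(O)COc1cccc2ccccc12
metoprolol,COCCc1ccc(OCC(O)CNC(C)C)cc1
warfarin,CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O
diazepam,CN1c2ccc(Cl)cc2C(=Nc2ccccc2)CC1=O
lorazepam,OC1N=C(c2ccccc2Cl)c2cc(Cl)ccc2NC1=O
phenytoin,O=C1NC(=O)C(N1)(c1ccccc1)c1ccccc1
carbamazepine,NC(=O)N1c2ccccc2C=Cc2ccccc21
lamotrigine,Nc1nnc(c(N)n1)-c1ccccc1Cl
gabapentin,NCC1(CC(=O)O)CCCCC1
pregabalin,CC(C)CC(CN)CC(=O)O
tramadol,CN(C)CC1CCCCC1(O)c1cccc(OC)c1
morphine,CN1CCC23c4c5ccc(O)c4OC2C(O)C=CC3C1C5
codeine,COc1ccc2CC3C4C=CC(O)C5Oc1c2C45CCN3C
lidocaine,CCN(CC)CC(=O)Nc1c(C)cccc1C
procaine,CCN(CC)CCOC(=O)c1ccc(N)cc1
ketamine,CNC1(c2ccccc2Cl)CCCCC1=O
fluoxetine,CNCCC(Oc1ccc(cc1)C(F)(F)F)c1ccccc1
sertraline,CNC1CCC(c2ccc(Cl)c(Cl)c2)c2ccccc12
citalopram,CN(C)CCCC1(OCc2cc(C#N)ccc21)c1ccc(F)cc1
venlafaxine,CN(C)CC(c1ccc(OC)cc1)C1(O)CCCCC1
bupropion,CC(NC(C)(C)C)C(=O)c1cccc(Cl)c1
amitriptyline,CN(C)CCC=C1c2ccccc2CCc2ccccc21
imipramine,CN(C)CCCN1c2ccccc2CCc2ccccc21
haloperidol,OC1(CCN(CCCC(=O)c2ccc(F)cc2)CC1)c1ccc(Cl)cc1
risperidone,CC1=C(CCN2CCC(CC2)c2noc3cc(F)ccc23)C(=O)N2CCCCC2=N1
quetiapine,OCCOCCN1CCN(CC1)C1=Nc2ccccc2Sc2ccccc12
olanzapine,CC1=CC2=C(S1)Nc1ccccc1N=C2N1CCN(C)CC1
clozapine,CN1CCN(CC1)C1=Nc2cc(Cl)ccc2Nc2ccccc12
metformin,CN(C)C(=N)NC(=N)N
glipizide,Cc1cnc(cn1)C(=O)NCCc1ccc(cc1)S(=O)(=O)NC(=O)NC1CCCCC1
omeprazole,COc1ccc2[nH]c(nc2c1)S(=O)Cc1ncc(C)c(OC)c1C
ranitidine,CNC(=C[N+](=O)[O-])NCCSCc1ccc(CN(C)C)o1
cimetidine,CC1=C(CSCCNC(=NC)NC#N)N=CN1
loratadine,CCOC(=O)N1CCC(=C2c3ccc(Cl)cc3CCc3cccnc32)CC1
cetirizine,OC(=O)COCCN1CCN(CC1)C(c1ccccc1)c1ccc(Cl)cc1
diphenhydramine,CN(C)CCOC(c1ccccc1)c1ccccc1
chlorpheniramine,CN(C)CCC(c1ccc(Cl)cc1)c1ccccn1
montelukast,CC(C)(O)c1ccccc1CCC(SCC1(CC(=O)O)CC1)c1cccc(C=Cc2ccc3ccc(Cl)cc3n2)c1
simvastatin,CCC(C)(C)C(=O)OC1CC(C)C=C2C=CC(C)C(CCC3CC(O)CC(=O)O3)C12
atorvastatin,CC(C)c1c(C(=O)Nc2ccccc2)c(-c2ccccc2)c(-c2ccc(F)cc2)n1CCC(O)CC(O)CC(=O)O
lovastatin,CCC(C)C(=O)OC1CC(C)C=C2C=CC(C)C(CCC3CC(O)CC(=O)O3)C12
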