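compound_id,formula,mw_printed,smiles,structure_approximate
strychnine,C21H22N2O2,334.41,C1CN2CC3=CCOC4CC(=O)N5C6C4C3CC2C61C7=CC=CC=C75,FALSE
tangeretin,C20H20O7,372.37,COc1ccc(-c2cc(=O)c3c(OC)c(OC)c(OC)c(OC)c3o2)cc1,FALSE
nobiletin,C21H22O8,402.39,COc1ccc(-c2cc(=O)c3c(OC)c(OC)c(OC)c(OC)c3o2)cc1OC,FALSE
amarogentin,C29H30O13,586.54,C=CC1C2CC(=O)OC(OC3OC(COC(=O)c4cc(O)cc(O)c4-c4cccc(O)c4)C(O)C(O)C3O)C2C=CO1,TRUE
phenol,C6H6O,94.11,Oc1ccccc1,FALSE
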