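quantity	value
annotated_spots_total	194
signature_correct_spots	190
unsupervised_agreeing_spots	186
pooled_spots_total	979
section_spots_1	242
section_spots_2	241
section_spots_3	252
section_spots_4	244
signature_tcs_total	798
signature_tcs_protein_coding	696
signature_tcs_non_coding	23
signature_tcs_non_annotated	79
signature_genes_protein_coding	678
signature_genes_non_coding	23
training_spots_fold1	133
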