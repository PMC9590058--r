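drug,class,age_class,weight_kg,adult_dose,adult_weight_kg,observed_dose,cl_child,cl_adult,reference_type
mab_alpha,monoclonal,child,12,10 mg/kg,70,10 mg/kg,,,per_kg_label
mab_alpha,monoclonal,child,45,10 mg/kg,70,10 mg/kg,,,per_kg_label
mab_beta,monoclonal,child,20,350 mg,70,,3.2 mL/h,8 mL/h,cl_based
mab_beta,monoclonal,adolescent,55,350 mg,70,290 mg,,,cl_based
ivig_pooled,polyclonal,child,18,400 mg/kg,70,400 mg/kg,,,per_kg_label
ivig_pooled,polyclonal,child,42,400 mg/kg,70,400 mg/kg,,,per_kg_label
ivig_pooled,polyclonal,preterm_neonate,1.5,400 mg/kg,70,250 mg/kg,,,investigator_selected
ivig_pooled,polyclonal,term_neonate,2.8,400 mg/kg,70,750 mg/kg,,,investigator_selected
enzyme_gamma,non_antibody,child,9,1 mg/kg,70,,0.9 mL/h/kg,0.6 mL/h/kg,cl_based
enzyme_gamma,non_antibody,child,33,1 mg/kg,70,1 mg/kg,,,per_kg_label
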