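label,composition,implication,note
C2H7N,C2H7N,quaternary,"ring-opening loss of the N plus two methyls; hallmark of quaternary aporphinium ions"
CH3NH2,CH5N,tertiary,"methylamine loss from tertiary N-methyl aporphines"
NH3,NH3,secondary,"ammonia loss from secondary (N-H) aporphines"
NH,NH,N_acyl_or_oxo,"imine-type loss seen for oxoaporphines"
C2H5NO,C2H5NO,N_acyl_or_oxo,"acetamide loss from N-acetyl aporphines"
CH3OH,CH4O,generic,
CH3O,CH3O,generic,"methoxy radical loss"
CO,CO,generic,
H2O,H2O,generic,
CH3,CH3,generic,"methyl radical loss"
C2H7N+CH3OH,C3H11NO,generic,"cumulative two-step loss matched precursor-relative"
C2H7N+CH3OH+CO,C4H11NO2,generic,"cumulative three-step loss matched precursor-relative"
CH3NH2+CH3OH,C2H9NO,generic,"cumulative two-step loss matched precursor-relative"
CH3NH2+CH3OH+CO,C3H9NO2,generic,"cumulative three-step loss matched precursor-relative"
NH3+CH3O,CH6NO,generic,"cumulative two-step loss matched precursor-relative"
CH3OH+CO,C2H4O2,generic,"cumulative two-step loss matched precursor-relative"
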