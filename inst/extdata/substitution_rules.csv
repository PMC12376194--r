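key_type,key,substitute_ugL,comment
analyte_id,manganese,0.01,named inorganic rule
analyte_id,nitrate_N,0.01,printed constant applied on the ug/L scale
analyte_id,lead,0.01,named inorganic rule
analyte_id,arsenic,0.1,named inorganic rule
analyte_id,uranium,0.1,named inorganic rule
analyte_class,pesticide,0.0001,organic class rule
analyte_class,pharmaceutical,0.0001,organic class rule
analyte_class,PFAS,0.0001,organic class rule
analyte_class,DBP,0.01,organic class rule (also cumulative organics)
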