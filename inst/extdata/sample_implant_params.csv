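patient_id,side,inclination_deg,anteversion_deg,stem_anteversion_deg,head_offset_mm,head_diameter_mm
P001,R,41.2,18.5,11.0,46.3,32
P002,L,38.7,23.1,8.4,49.0,32
P003,R,44.0,15.9,14.2,45.1,32
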