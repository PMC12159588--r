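name,x,y,z
ASIS_right,120,5,85
ASIS_left,-120,5,85
PTUB_right,25,5,5
PTUB_left,-25,5,5
EPI_lateral,40,0,-400
EPI_medial,-40,0,-400
knee_center,0,0,-400
HJC,0,0,0
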