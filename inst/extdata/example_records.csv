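experiment_id,condition,phase,time_min,t_half_ms,f_m
cell001,wt,G1,32,696.9,0.949
cell002,wt,S,32,574,0.946
cell003,wt,G2,135,480.6,0.928
cell004,wt,S,129,436.9,1.002
cell005,wt,G2,134,525.6,1.015
cell006,wt,G2,113,350,1.002
cell007,wt,S,67,491.9,0.931
cell008,wt,G2,6,461.1,1.007
cell009,wt,G1,163,689.3,0.991
cell010,wt,S,143,671.4,0.951
cell011,rna_binding_mutant,G1,40,271.4,0.906
cell012,rna_binding_mutant,G1,87,143.6,0.96
cell013,rna_binding_mutant,G1,110,388.1,0.912
cell014,rna_binding_mutant,G1,157,382.2,0.947
cell015,rna_binding_mutant,G1,7,367.3,0.949
cell016,rna_binding_mutant,G1,49,368.4,0.912
cell017,rna_binding_mutant,S,77,237.7,0.923
cell018,rna_binding_mutant,S,142,364.7,0.923
cell019,rna_binding_mutant,G1,149,436,1.037
cell020,rna_binding_mutant,S,46,284.6,1.005
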