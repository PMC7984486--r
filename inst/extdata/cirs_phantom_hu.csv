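name,hu_scale_measured
Lung Inhale,193.7
Lung Exhale,505.3
Adipose,930.7
Breast 50/50,966.1
Plastic Water,998.3
True Water,999.8
Muscle,1048.9
Liver,1047.5
Bone 200 mg/cc,1212.2
Bone 800 mg/cc,1871.7
Bone 1000 mg/cc,2079.9
Bone 1250 mg/cc,2321.0
Bone 1500 mg/cc,2583.4
Bone 1750 mg/cc,2787.0
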