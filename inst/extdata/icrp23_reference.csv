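name,category,density,H,C,N,O,Ca,P,Na,Mg,S,Cl,K,Fe,I
Adipose,fat,0.95,11.4,59.8,0.7,27.8,0,0,0.1,0,0.1,0.1,0,0,0
Yellow marrow,fat,0.98,11.5,64.4,0.7,23.1,0,0,0.1,0,0.1,0.1,0,0,0
Red marrow,fat,1.03,10.5,41.4,3.4,43.9,0,0.1,0,0,0.2,0.2,0.2,0.1,0
Lung (inflated),soft,0.26,10.3,10.5,3.1,74.9,0,0.2,0.2,0,0.3,0.3,0.2,0,0
GI tract,soft,1.03,10.6,11.5,2.2,75.1,0,0.1,0.1,0,0.1,0.2,0.1,0,0
Lymph,soft,1.03,10.8,4.1,1.1,83.2,0,0,0.3,0,0.1,0.4,0,0,0
Brain,soft,1.04,10.7,14.5,2.2,71.2,0,0.4,0.2,0,0.2,0.3,0.3,0,0
Pancreas,soft,1.04,10.6,16.9,2.2,69.4,0,0.2,0.2,0,0.1,0.2,0.2,0,0
Testis,soft,1.04,10.6,9.9,2,76.6,0,0.1,0.2,0,0.2,0.2,0.2,0,0
Kidney,soft,1.05,10.3,13.2,3,72.4,0.1,0.2,0.2,0,0.2,0.2,0.2,0,0
Lung (deflated),soft,1.05,10.3,10.5,3.1,74.9,0,0.2,0.2,0,0.3,0.3,0.2,0,0
Muscle,soft,1.05,10.2,14.3,3.4,71,0,0.2,0.1,0,0.3,0.1,0.4,0,0
Ovary,soft,1.05,10.5,9.3,2.4,76.8,0,0.2,0.2,0,0.2,0.2,0.2,0,0
Thyroid,soft,1.05,10.4,11.9,2.4,74.5,0,0.1,0.2,0,0.1,0.2,0.1,0,0.1
Blood,soft,1.06,10.2,11,3.3,74.5,0,0.1,0.1,0,0.2,0.3,0.2,0.1,0
Heart,soft,1.06,10.3,12.1,3.2,73.4,0,0.1,0.1,0,0.2,0.3,0.2,0.1,0
Liver,soft,1.06,10.2,13.9,3,71.6,0,0.3,0.2,0,0.3,0.2,0.3,0,0
Spleen,soft,1.06,10.3,11.3,3.2,74.1,0,0.3,0.1,0,0.2,0.2,0.3,0,0
Eye lens,soft,1.07,9.6,19.5,5.7,64.6,0,0.1,0.1,0,0.3,0.1,0,0,0
Skin,soft,1.09,10,20.4,4.2,64.5,0,0.1,0.2,0,0.2,0.3,0.1,0,0
Cartilage,soft,1.1,9.6,9.9,2.2,74.4,0,2.2,0.5,0,0.9,0.3,0,0,0
Skeleton-spongiosa,bone,1.18,8.5,40.4,2.8,36.7,7.4,3.4,0.1,0.1,0.2,0.2,0.1,0.1,0
Skeleton-sacrum,bone,1.29,7.4,30.2,3.7,43.8,9.8,4.5,0,0.1,0.2,0.1,0.1,0.1,0
Skeleton-femur,bone,1.33,7,34.5,2.8,36.8,12.9,5.5,0.1,0.1,0.2,0.1,0,0,0
Skeleton-vertebra (L3),bone,1.33,7,28.7,3.8,43.7,11.1,5.1,0,0.1,0.2,0.1,0.1,0.1,0
Skeleton-ribs (2-6),bone,1.41,6.4,26.3,3.9,43.6,13.1,6,0.1,0.1,0.3,0.1,0.1,0,0
Skeleton-vertebra (C4),bone,1.42,6.3,26.1,3.9,43.5,13.3,6.1,0.1,0.1,0.3,0.1,0.1,0.1,0
Skeleton-humerus,bone,1.46,6,31.4,3.1,36.9,15.2,7,0.1,0.1,0.2,0,0,0,0
Skeleton-ribs (10),bone,1.52,5.6,23.5,4,43.4,15.6,7.2,0.1,0.1,0.3,0.1,0.1,0,0
Skeleton-cranium,bone,1.61,5,21.2,4,43.5,17.6,8.1,0.1,0.2,0.3,0,0,0,0
Skeleton-mandible,bone,1.68,4.6,19.9,4.1,43.5,18.7,8.6,0.1,0.2,0.3,0,0,0,0
Skeleton-cortical bone,bone,1.92,3.4,15.5,4.2,43.5,22.5,10.3,0.1,0.2,0.3,0,0,0,0
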