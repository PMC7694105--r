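variable,age,weight_kg,stature_cm,triceps_mm,subscapular_mm,supraspinal_mm,medial_calf_mm,arm_girth_cm,calf_girth_cm,humerus_cm,femur_cm,ffm_kg,phase_angle,resistance_ohm,reactance_ohm
age,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0
weight_kg,0,1,0.475,0.2375,0.2375,0.2375,0.2375,0.57,0.57,0.38,0.38,0.9025,0.095,-0.475,-0.2375
stature_cm,0,0.475,1,0,0,0,0,0.19,0.19,0.475,0.475,0.5225,0,0.095,0
triceps_mm,0,0.2375,0,1,0.57,0.57,0.57,0.19,0.19,0,0,0,-0.095,0.1425,0
subscapular_mm,0,0.2375,0,0.57,1,0.57,0.57,0.19,0.19,0,0,0,-0.095,0.1425,0
supraspinal_mm,0,0.2375,0,0.57,0.57,1,0.57,0.19,0.19,0,0,0,-0.095,0.1425,0
medial_calf_mm,0,0.2375,0,0.57,0.57,0.57,1,0.19,0.19,0,0,0,-0.095,0.1425,0
arm_girth_cm,0,0.57,0.19,0.19,0.19,0.19,0.19,1,0.475,0.285,0.285,0.57,0.095,-0.38,-0.19
calf_girth_cm,0,0.57,0.19,0.19,0.19,0.19,0.19,0.475,1,0.285,0.285,0.57,0.095,-0.38,-0.19
humerus_cm,0,0.38,0.475,0,0,0,0,0.285,0.285,1,0.38,0.38,0,-0.1425,-0.0475
femur_cm,0,0.38,0.475,0,0,0,0,0.285,0.285,0.38,1,0.38,0,-0.1425,-0.0475
ffm_kg,0,0.9025,0.5225,0,0,0,0,0.57,0.57,0.38,0.38,1,0.1425,-0.57,-0.285
phase_angle,0,0.095,0,-0.095,-0.095,-0.095,-0.095,0.095,0.095,0,0,0.1425,1,-0.095,0.5225
resistance_ohm,0,-0.475,0.095,0.1425,0.1425,0.1425,0.1425,-0.38,-0.38,-0.1425,-0.1425,-0.57,-0.095,1,0.665
reactance_ohm,0,-0.2375,0,0,0,0,0,-0.19,-0.19,-0.0475,-0.0475,-0.285,0.5225,0.665,1
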