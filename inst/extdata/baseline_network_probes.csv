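name,vessel_id,axial_fraction
aortic_root,ascending_aorta,0.050000000000000003
brachial,brachial_L,0.5
renal_main_L,renal_main_L,0.5
renal_main_R,renal_main_R,0.5
renal_seg_L1,renal_seg_L1,0.5
renal_seg_L2,renal_seg_L2,0.5
renal_seg_L3,renal_seg_L3,0.5
renal_seg_L4,renal_seg_L4,0.5
renal_seg_L5,renal_seg_L5,0.5
renal_seg_R1,renal_seg_R1,0.5
renal_seg_R2,renal_seg_R2,0.5
renal_seg_R3,renal_seg_R3,0.5
renal_seg_R4,renal_seg_R4,0.5
renal_seg_R5,renal_seg_R5,0.5
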