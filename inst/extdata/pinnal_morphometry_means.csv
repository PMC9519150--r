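label,slit_area_mm2,cavity_volume_mm3,pinna_protrusion_mm,septum_width_mm
APC,0.16,0.14,0.39,0.42
PPC,0.16,0.15,0.45,0.42
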