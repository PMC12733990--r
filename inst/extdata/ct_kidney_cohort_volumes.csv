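volume_type,patients,avg_slices,slice_spacing_mm
complete,3215,15.2,3.0
interpolated,632,10.8,2.5
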