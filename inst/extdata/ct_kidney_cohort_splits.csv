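split,patients,ct_slices,patients_with_pathology
training,2693,8712,1885
validation,577,1867,404
test,577,1867,404
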