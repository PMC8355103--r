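assay_id	role
UniSp2	spike_in_extraction
UniSp4	spike_in_extraction
UniSp6	spike_in_rt
miR-23a	hemolysis
miR-451a	hemolysis
miR-93-5p	candidate
miR-1246	candidate
miR-223-3p	candidate
let-7g-5p	candidate
miR-21-5p	candidate
cand-01	candidate
cand-02	candidate
cand-03	candidate
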