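gene	bmi	wc	whr	pbf
CHRNA3	0.1730	0.0360	0.0320	0.4870
CHRNA4	0.2380	0.2220	0.2150	0.1460
CHRNA5	0.3050	0.0001	0.0160	0.5870
CHRNA6	0.6352	0.4033	0.3575	0.3671
CHRNB2	0.3840	0.3010	0.0190	0.2110
CHRNB3	0.0470	0.0370	0.1980	0.0300
CHRNB4	0.1890	0.0560	0.0950	0.3310
gene_family	0.1970	0.0001	0.0001	0.2910
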