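label_id	roi_name
17	left_hippocampal
53	right_hippocampal
1001	left_temporal
1006	left_temporal
1007	left_temporal
1009	left_temporal
1015	left_temporal
1016	left_temporal
1030	left_temporal
1033	left_temporal
1034	left_temporal
2001	right_temporal
2006	right_temporal
2007	right_temporal
2009	right_temporal
2015	right_temporal
2016	right_temporal
2030	right_temporal
2033	right_temporal
2034	right_temporal
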