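species	ds	perc_rank	dc_mean	dc_sd
Berylline Hummingbird	11.680	4	0.917	0.139
Blue-throated Mountain-gem	20.905	1	0.828	0.175
Broad-billed Hummingbird	-0.333	6	0.861	0.160
Broad-tailed Hummingbird	-7.596	NA	NA	NA
Bumblebee Hummingbird	-18.680	11	0.975	0.027
Calliope Hummingbird	-13.180	10	0.911	0.152
Costa's Hummingbird	-17.566	9	0.872	0.174
Mexican Violetear	17.712	3	0.843	0.178
Rivoli's Hummingbird	24.992	2	0.968	0.063
Ruby-throated Hummingbird	-6.552	NA	NA	NA
Rufous Hummingbird	-12.541	8	0.907	0.116
Violet-crowned Hummingbird	4.151	5	0.911	0.128
White-eared Hummingbird	-2.990	7	0.921	0.126
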