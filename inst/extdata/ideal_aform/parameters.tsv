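parameter	value
twist_deg	32.7
rise_A	2.81
x_disp_A	-3.7908
y_disp_A	0.2625
inclination_deg	12.256
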