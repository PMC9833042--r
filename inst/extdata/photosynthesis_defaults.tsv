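# Published treatment-mean photosynthetic parameters for cold (10C)- and
# warm (30C)-grown Arabidopsis measured at 10 and 30 degC; used as the
# default generating truth of the synthetic gas-exchange study.
# v_cmax, a400, r_d: umol CO2 m-2 s-1; j_max: umol e- m-2 s-1;
# g_s: mol H2O m-2 s-1; g_m: mol CO2 m-2 s-1; rubisco_sites: umol m-2.
growth	measurement	a400	g_s	j_max	v_cmax	r_d	g_m	rubisco_sites
10C	10	19.2	0.26	133.1	55.8	1.1	0.114	14.4
10C	30	13.2	0.20	190.6	108.1	3.6	0.142	14.4
30C	10	11.8	0.44	74.1	40.1	1.1	0.131	8.9
30C	30	14.7	0.37	138.8	100.9	2.6	0.204	8.9
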