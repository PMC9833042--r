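# Published treatment-mean leaf traits for Arabidopsis grown at three air
# temperatures: Rubisco catalytic-site content (umol m-2), total soluble
# protein (g m-2), chlorophyll (mmol m-2), Rubisco/chlorophyll (mmol mol-1),
# specific leaf area (m2 kg-1). se_* columns are standard errors.
growth	rubisco_sites	se_rubisco_sites	soluble_protein	se_soluble_protein	chlorophyll	se_chlorophyll	rubisco_chl	se_rubisco_chl	sla	se_sla
10C	14.4	0.83	4.88	0.9	0.852	0.14	24.6	1.2	3.24	0.42
20C	10.4	0.32	3.39	0.4	0.656	0.064	19.9	1.7	1.60	0.11
30C	8.9	0.61	2.49	0.5	0.525	0.074	19.8	1.1	1.24	0.11
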