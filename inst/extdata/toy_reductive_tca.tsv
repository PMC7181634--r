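id	equation	lb	ub	subsystem
GLY1	1 GLC_e + 2 NAD_c + 2 ADP_c -> 2 PEP_c + 2 NADH_c + 2 ATP_c	0	1000	glycolysis
GLY2	1 GLC_e + 2 NAD_c + 2 ADP_c -> 2 PEP_c + 2 NADH_c + 2 ATP_c	0	1000	glycolysis
GOLU1	1 GOL_e + 2 NAD_c -> 1 PEP_c + 2 NADH_c	0	1000	glycerol assimilation
GOLU2	1 GOL_e + 2 NAD_c -> 1 PEP_c + 2 NADH_c	0	1000	glycerol assimilation
PCKA	1 PEP_c + 1 CO2_e + 1 ADP_c -> 1 OAA_c + 1 ATP_c	0	1000	anaplerosis
MDH	1 OAA_c + 1 NADH_c <=> 1 MAL_c + 1 NAD_c	-1000	1000	reductive TCA
FUMC	1 MAL_c <=> 1 FUM_c	-1000	1000	reductive TCA
FRD	1 FUM_c + 1 MQH2_c -> 1 SUC_e + 1 MQ_c	0	1000	reductive TCA
NDH1	1 NADH_c + 1 MQ_c -> 1 NAD_c + 1 MQH2_c	0	1000	respiration
NDH2	1 NADH_c + 1 MQ_c -> 1 NAD_c + 1 MQH2_c	0	1000	respiration
FDH	1 FOR_e + 1 MQ_c -> 1 CO2_e + 1 MQH2_c	0	1000	respiration
PYK	1 PEP_c + 1 ADP_c -> 1 PYR_c + 1 ATP_c	0	1000	glycolysis
LDHA	1 PYR_c + 1 NADH_c -> 1 LAC_e + 1 NAD_c	0	1000	byproduct
PFL	1 PYR_c -> 1 ACO_c + 1 FOR_e	0	1000	byproduct
PTA	1 ACO_c -> 1 ACP_c	0	1000	byproduct
ACKA	1 ACP_c + 1 ADP_c -> 1 ACT_e + 1 ATP_c	0	1000	byproduct
PYRX	1 PYR_c -> 1 PYR_e	0	1000	byproduct
ME	1 MAL_c + 1 NAD_c -> 1 PYR_c + 1 CO2_e + 1 NADH_c	0	1000	anaplerosis
ATPM	1 ATP_c -> 1 ADP_c	1	1000	maintenance
BIOMASS	1 PYR_c + 0.5 OAA_c + 10 ATP_c + 0.5 NADH_c -> 1 BIOM_e + 10 ADP_c + 0.5 NAD_c	0	1000	biomass
EX_glc	1 GLC_e <=>	-10	1000	exchange
EX_gol	1 GOL_e ->	0	1000	exchange
EX_co2	1 CO2_e <=>	-1000	1000	exchange
EX_suc	1 SUC_e ->	0	1000	exchange
EX_lac	1 LAC_e ->	0	1000	exchange
EX_for	1 FOR_e ->	0	1000	exchange
EX_act	1 ACT_e ->	0	1000	exchange
EX_pyr	1 PYR_e ->	0	1000	exchange
EX_biom	1 BIOM_e ->	0	1000	exchange
CYC1	1 X_c <=> 1 Y_c	-1000	1000	loop test
CYC2	1 X_c <=> 1 Y_c	-1000	1000	loop test
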