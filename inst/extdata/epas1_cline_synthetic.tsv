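# SYNTHETIC stand-in for the deposited Epas1 sampling-locality table:
# binomial allele counts drawn from a sigmoid cline (center 1399.5 m,
# width 400 m, pmin 0.02, pmax 0.84; regional sites add logit-normal
# scatter, sd 1). Regenerate with scripts/make_extdata.R (seed 20191).
locality	elevation_m	allele_H_count	total_alleles	transect
transect_01	360	1	28	TRUE
transect_02	650	1	24	TRUE
transect_03	900	1	24	TRUE
transect_04	1100	2	20	TRUE
transect_05	1250	3	24	TRUE
transect_06	1400	8	28	TRUE
transect_07	1600	19	24	TRUE
transect_08	2000	16	20	TRUE
transect_09	3000	17	24	TRUE
transect_10	4350	30	32	TRUE
regional_01	150	0	16	FALSE
regional_02	250	0	20	FALSE
regional_03	500	0	20	FALSE
regional_04	800	0	20	FALSE
regional_05	1200	1	24	FALSE
regional_06	1500	21	24	FALSE
regional_07	1800	14	20	FALSE
regional_08	2100	18	24	FALSE
regional_09	2400	23	24	FALSE
regional_10	2700	18	20	FALSE
regional_11	3000	21	24	FALSE
regional_12	3300	19	20	FALSE
regional_13	3600	25	28	FALSE
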