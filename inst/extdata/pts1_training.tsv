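name	terminus	label
ACOX3_like_synthetic	AKSNLSVSGSKL	1
pos_skl_2	MESTPKAHLSKL	1
pos_skl_3	GGLNPSRAQSKL	1
pos_skl_4	TRLSEVKPHSKL	1
pos_skl_5	VKGNSLQPHSKL	1
pos_skl_6	GQNHKSLPVSKL	1
pos_akl_1	QSVNPLRGHAKL	1
pos_akl_2	SPLMGKTNQAKL	1
pos_akl_3	LSGQKNPHTAKL	1
pos_srl_1	DKLGVSPNKSRL	1
pos_srl_2	ESGKLPVRHSRL	1
pos_srl_3	NQAKSGLPKSRL	1
pos_srl_4	TGLKHSNPQSRL	1
pos_srl_5	TPSGKLQNHSRL	1
pos_ckl_1	LVHGKQSNPCKL	1
pos_ckl_2	SGPKLNTRHCKL	1
pos_skm_1	AQNKLGSPHSKM	1
pos_skm_2	GSKLNPQTRSKM	1
pos_arl_1	HSPGLKNQVARL	1
pos_shl_1	KGQSLNPTVSHL	1
pos_ahl_1	RLNGQSPKTAHL	1
pos_crl_1	QPLESVSKNCRL	1
pos_crl_2	AGLQETNPKCRL	1
pos_crl_3	SLESVSKHQCRL	1
pos_crl_4	NHQGKSLPVCRL	1
pos_srm_1	GKNSPQLVTSRM	1
pos_akm_1	PLHGSKQNVAKM	1
pos_ssl_1	NGSKLPQHTSSL	1
pos_anl_1	QKTGSLPNHANL	1
pos_prl_1	SGQKLHNTVPRL	1
neg_crl_dL	AQPLESVSKNCR	0
neg_skl_dL	TAKSNLSVSGSK	0
neg_skl_dL2	AGGLNPSRAQSK	0
neg_srl_dL	ADKLGVSPNKSR	0
neg_ckl_dL	ALVHGKQSNPCK	0
neg_acid_1	MEEAGSDLEEGD	0
neg_acid_2	SPDLENQGTDEE	0
neg_acid_3	GVDMEQNSLDDE	0
neg_acid_4	LKDETNPGQSEG	0
neg_cyt_1	VESGDNLQPTGA	0
neg_cyt_2	NTDSGLVPQEGV	0
neg_cyt_3	PGQEVDNSLTAG	0
neg_cyt_4	MDGSLNEQPTVD	0
neg_cyt_5	SGVPLDTNQEAV	0
neg_cyt_6	EQGTDVSLNPGM	0
neg_cyt_7	TDNGPQSVLEAD	0
neg_cyt_8	GLSEDPNVTQGE	0
neg_cyt_9	PVQDGTNSELAG	0
neg_cyt_10	DSGNVLPQTEDA	0
neg_cyt_11	QEPTVGDSNLGE	0
neg_cyt_12	VGTDQPSENLAD	0
neg_cyt_13	NPELDGQTVSGD	0
neg_cyt_14	GDQVSPTNLEGE	0
neg_cyt_15	SVEPGDQNTLGA	0
neg_cyt_16	TQGNDPVESLGD	0
neg_cyt_17	DPGVTQNSEGLA	0
neg_cyt_18	EGSDNQPTVGLD	0
neg_cyt_19	LGDPESQVTNGA	0
neg_cyt_20	QVTGEDNPSCLE	0
neg_cyt_21	NDGEQPTSVCGA	0
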