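domain_name	accession	role
HisKA	PF00512	phosphotransfer_dimerization
HisKA_2	PF07568	phosphotransfer_dimerization
HisKA_3	PF07730	phosphotransfer_dimerization
HWE_HK	PF07536	phosphotransfer_dimerization
HATPase_c	PF02518	phosphotransfer_atpase
HATPase		phosphotransfer_atpase
Hpt	PF01627	hpt
REC	PF00072	receiver
Response_reg	PF00072	receiver
PAS	PF13426	sensor
PAS_3	PF08447	sensor
PAS_4	PF08448	sensor
PAS_11	PF14598	sensor
GAF	PF13492	sensor
GAF_2	PF13185	sensor
Cache	PF02743	sensor
sCache	PF02743	sensor
dCache_1	PF02743	sensor
MEDS	PF14417	sensor
PocR	PF10114	sensor
HisKA_7TM	PF16927	sensor
HisKA_4TM	PF16926	sensor
HAMP	PF00672	sensor
BAT	PF15915	output_dna_binding
HTH_10	PF04967	output_dna_binding
HTH		output_dna_binding
wHTH		output_dna_binding
HxlR	PF01638	output_dna_binding
HTH_20	PF12840	output_dna_binding
CheB	PF01339	output_enzymatic
CheB_methylest	PF01339	output_enzymatic
KaiC	PF06745	output_enzymatic
iKaiC	PF06745	output_enzymatic
DUF835	PF05763	output_enzymatic
Glyco_transf_2_3	PF13641	output_enzymatic
BcsA	PF13641	output_enzymatic
GGDEF	PF00990	output_enzymatic
EAL	PF00563	output_enzymatic
PP2C	PF07228	output_enzymatic
Thioredoxin_reductase	PF07992	output_enzymatic
PPDK	PF01326	output_enzymatic
HalX	PF08663	output_halx
HalOD1	PF18545	output_novel
HalOD2	PF18547	output_novel
MetOD1	PF18546	output_novel
MetOD2	PF18548	output_novel
MetOD3		output_novel
MetOD4		output_novel
MetOD5		output_novel
NitrOD1	PF18549	output_novel
NitrOD2	PF18550	output_novel
NitrOD3		output_novel
NitrOD4		output_novel
NitrOD5	PF11537	output_novel
TackOD1	PF18551	output_novel
AcidOD1		output_novel
MCPsignal	PF00015	output_other
TPR	PF13414	output_other
TPR-like	PF13414	output_other
DUF1724	PF08350	output_other
CheW	PF01584	chew
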