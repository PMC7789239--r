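gene	class
HLA-A	MHC-I
HLA-B	MHC-I
HLA-C	MHC-I
HLA-E	MHC-I
HLA-F	MHC-I
HLA-G	MHC-I
B2M	MHC-I
TAP1	MHC-I
TAP2	MHC-I
TAPBP	MHC-I
NLRC5	MHC-I
MICB	MHC-I
HLA-DRA	MHC-II
HLA-DRB1	MHC-II
HLA-DQA1	MHC-II
HLA-DQB1	MHC-II
HLA-DPA1	MHC-II
HLA-DPB1	MHC-II
HLA-DMA	MHC-II
HLA-DMB	MHC-II
HLA-DOA	MHC-II
HLA-DOB	MHC-II
CIITA	MHC-II
CD27	checkpoint stimulator
CD28	checkpoint stimulator
CD40	checkpoint stimulator
CD40LG	checkpoint stimulator
CD70	checkpoint stimulator
CD80	checkpoint stimulator
CD86	checkpoint stimulator
ICOS	checkpoint stimulator
ICOSLG	checkpoint stimulator
TNFRSF4	checkpoint stimulator
TNFSF4	checkpoint stimulator
TNFRSF9	checkpoint stimulator
TNFSF9	checkpoint stimulator
TNFRSF18	checkpoint stimulator
TNFSF18	checkpoint stimulator
TNFRSF14	checkpoint stimulator
TNFSF14	checkpoint stimulator
TNFRSF13B	checkpoint stimulator
TNFSF13	checkpoint stimulator
TNFSF13B	checkpoint stimulator
CD226	checkpoint stimulator
CD2	checkpoint stimulator
IL2RA	checkpoint stimulator
ENTPD1	checkpoint stimulator
HMGB1	checkpoint stimulator
IFNG	checkpoint stimulator
TNFSF8	checkpoint stimulator
CTLA4	checkpoint inhibitor
PDCD1	checkpoint inhibitor
CD274	checkpoint inhibitor
PDCD1LG2	checkpoint inhibitor
LAG3	checkpoint inhibitor
HAVCR2	checkpoint inhibitor
TIGIT	checkpoint inhibitor
BTLA	checkpoint inhibitor
VTCN1	checkpoint inhibitor
CD276	checkpoint inhibitor
IDO1	checkpoint inhibitor
ADORA2A	checkpoint inhibitor
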