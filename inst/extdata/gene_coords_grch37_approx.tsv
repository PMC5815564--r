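gene	chrom	start	end
CTNNB1	chr3	41240000	41281000
APC	chr5	112043000	112181000
RSPO2	chr8	108911000	109095000
RNF43	chr17	56431000	56495000
ZNRF3	chr22	29278000	29448000
MLH1	chr3	37035000	37092000
MSH2	chr2	47630000	47710000
MSH6	chr2	48010000	48034000
PMS2	chr7	6013000	6048000
PTEN	chr10	89623000	89729000
TP53	chr17	7571000	7591000
SPOP	chr17	47676000	47756000
FOXA1	chr14	38059000	38065000
KMT2C	chr7	151832000	152133000
KMT2D	chr12	49412000	49453000
CHD1	chr5	98190000	98262000
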