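description	n_genes
TGFb-responsive genes in p53-depleted MDA-MB-231 cells	105
Mesenchymal stromal cells cocultured with CD133+ hematopoietic stem cells	21
TGFb-induced transition in irradiated HMECs	32
Trophoblast invasion-related genes	648
Integrin a6b4 overexpression in MDA-MB-435 cells	263
Ezrin knockdown in SW480	26
Wild-type versus dominant-negative SNAIL in MDA-MB-231 cells	50
Wild-type versus mutant NM23-H1 in MDA-MB-435 cells	44
Non-lens betagamma-crystallin and trefoil factor complex	55
Central versus peripheral zones of pancreatic carcinoma	756
Normal versus constitutively-active-RhoA-transfected HMECs	135
Class IIb HLH factors E2-2A/E2-2B overexpression in MDCK cells	147
Epigenetically regulated genes in MDA-MB-468 versus MDA-MB-468LN	136
Migratory cells in the Drosophila ovary	33
MIR-520C transfection in MCF-7 cells	113
MIR-373 transfection in MCF-7 cells	128
Mesenchymal versus epithelial cells	186
CCL25-induced mesenchymal stem cells	105
Migratory glioma cell lines	89
CD146 downmodulation in MDA-MB-231 cells	45
TGFb-treated keratinocytes	92
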