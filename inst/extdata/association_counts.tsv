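population	phenotype	hom_alt	het	hom_ref
Jinyang Silky	case	23	0	0
Kuaida Silky	case	41	0	0
Lanping Silky	case	16	0	0
Silkie	case	257	0	0
CAURP F1	obligate_het	0	27	0
Silkie crossbred	obligate_het	0	13	0
Aijiao Yellow	control	0	0	10
Anak	control	0	0	10
Anyi Gray	control	0	0	10
Baier Yellow	control	0	0	10
Beijing You	control	0	0	20
Bian	control	0	0	10
Chahua	control	0	0	10
Chongren Partridge	control	0	0	10
Dagu	control	0	0	10
Dongxiang Blue-Eggshell	control	0	0	10
Gushi	control	0	0	10
Henan Game	control	0	0	10
Huiyang Bearded	control	0	0	20
Jinhu Black-Bone	control	0	0	10
Langshan	control	0	0	10
Luyuan	control	0	0	10
Qingyuan Partridge	control	0	0	10
Red Jungle Fowl	control	0	0	36
Shiqiza	control	0	0	10
Shouguang	control	0	0	10
Tibetan	control	0	0	10
Wenchang	control	0	0	10
White Leghorn	control	0	0	24
White Rock	control	0	0	21
Xianju	control	0	0	10
Xiaoshan	control	0	0	10
Youxi Partridge	control	0	0	10
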