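pathway_id	metabolite_id	pathway_name
map00500	gc_043	Starch and sucrose metabolism
map00500	gc_132	Starch and sucrose metabolism
map00500	polar_001	Starch and sucrose metabolism
map00500	polar_007	Starch and sucrose metabolism
map00500	polar_014	Starch and sucrose metabolism
map00500	polar_020	Starch and sucrose metabolism
map00500	polar_058	Starch and sucrose metabolism
map00500	polar_088	Starch and sucrose metabolism
map00052	gc_007	Galactose metabolism
map00052	gc_014	Galactose metabolism
map00052	gc_035	Galactose metabolism
map00052	polar_027	Galactose metabolism
map00052	polar_033	Galactose metabolism
map00052	polar_040	Galactose metabolism
map00052	polar_046	Galactose metabolism
map00052	polar_058	Galactose metabolism
map00380	gc_220	Tryptophan metabolism
map00380	polar_029	Tryptophan metabolism
map00380	polar_053	Tryptophan metabolism
map00380	polar_059	Tryptophan metabolism
map00380	polar_066	Tryptophan metabolism
map00380	polar_072	Tryptophan metabolism
map00380	polar_079	Tryptophan metabolism
map00380	polar_106	Tryptophan metabolism
map00340	gc_057	Histidine metabolism
map00340	gc_213	Histidine metabolism
map00340	lipid_005	Histidine metabolism
map00340	lipid_006	Histidine metabolism
map00340	lipid_013	Histidine metabolism
map00340	polar_024	Histidine metabolism
map00340	polar_118	Histidine metabolism
map00340	polar_125	Histidine metabolism
map00480	gc_006	Glutathione metabolism
map00480	gc_013	Glutathione metabolism
map00480	gc_019	Glutathione metabolism
map00480	gc_026	Glutathione metabolism
map00480	gc_197	Glutathione metabolism
map00480	lipid_004	Glutathione metabolism
map00480	polar_006	Glutathione metabolism
map00480	polar_106	Glutathione metabolism
map00350	gc_032	Tyrosine metabolism
map00350	gc_039	Tyrosine metabolism
map00350	gc_045	Tyrosine metabolism
map00350	gc_052	Tyrosine metabolism
map00350	gc_113	Tyrosine metabolism
map00350	gc_168	Tyrosine metabolism
map00350	gc_214	Tyrosine metabolism
map00350	polar_029	Tyrosine metabolism
map00400	gc_023	Phenylalanine, tyrosine and tryptophan biosynthesis
map00400	gc_049	Phenylalanine, tyrosine and tryptophan biosynthesis
map00400	gc_058	Phenylalanine, tyrosine and tryptophan biosynthesis
map00400	gc_065	Phenylalanine, tyrosine and tryptophan biosynthesis
map00400	gc_071	Phenylalanine, tyrosine and tryptophan biosynthesis
map00400	gc_207	Phenylalanine, tyrosine and tryptophan biosynthesis
map00400	gc_216	Phenylalanine, tyrosine and tryptophan biosynthesis
map00051	gc_035	Fructose and mannose metabolism
map00051	gc_091	Fructose and mannose metabolism
map00051	gc_095	Fructose and mannose metabolism
map00051	gc_097	Fructose and mannose metabolism
map00051	gc_104	Fructose and mannose metabolism
map00051	gc_111	Fructose and mannose metabolism
map00051	lipid_004	Fructose and mannose metabolism
map00051	polar_005	Fructose and mannose metabolism
map00330	gc_116	Arginine and proline metabolism
map00330	gc_117	Arginine and proline metabolism
map00330	gc_124	Arginine and proline metabolism
map00330	gc_129	Arginine and proline metabolism
map00330	gc_130	Arginine and proline metabolism
map00330	gc_137	Arginine and proline metabolism
map00330	gc_152	Arginine and proline metabolism
map00330	lipid_010	Arginine and proline metabolism
map00524	gc_016	Neomycin, kanamycin and gentamicin biosynthesis
map00524	gc_143	Neomycin, kanamycin and gentamicin biosynthesis
map00524	gc_150	Neomycin, kanamycin and gentamicin biosynthesis
map00524	gc_156	Neomycin, kanamycin and gentamicin biosynthesis
map00524	gc_172	Neomycin, kanamycin and gentamicin biosynthesis
map00524	polar_004	Neomycin, kanamycin and gentamicin biosynthesis
map00250	gc_025	Alanine, aspartate and glutamate metabolism
map00250	gc_082	Alanine, aspartate and glutamate metabolism
map00250	gc_167	Alanine, aspartate and glutamate metabolism
map00250	polar_006	Alanine, aspartate and glutamate metabolism
map00250	polar_039	Alanine, aspartate and glutamate metabolism
map00250	polar_048	Alanine, aspartate and glutamate metabolism
map00250	polar_122	Alanine, aspartate and glutamate metabolism
map00260	gc_048	Glycine, serine and threonine metabolism
map00260	gc_123	Glycine, serine and threonine metabolism
map00260	gc_132	Glycine, serine and threonine metabolism
map00260	gc_175	Glycine, serine and threonine metabolism
map00260	lipid_004	Glycine, serine and threonine metabolism
map00260	polar_042	Glycine, serine and threonine metabolism
map00260	polar_090	Glycine, serine and threonine metabolism
map00071	gc_002	Fatty acid degradation
map00071	gc_016	Fatty acid degradation
map00071	gc_122	Fatty acid degradation
map00071	gc_155	Fatty acid degradation
map00071	polar_019	Fatty acid degradation
map00071	polar_097	Fatty acid degradation
map00230	gc_038	Purine metabolism
map00230	gc_212	Purine metabolism
map00230	gc_214	Purine metabolism
map00230	lipid_005	Purine metabolism
map00230	polar_068	Purine metabolism
map00230	polar_119	Purine metabolism
map00240	gc_076	Pyrimidine metabolism
map00240	gc_108	Pyrimidine metabolism
map00240	gc_180	Pyrimidine metabolism
map00240	gc_203	Pyrimidine metabolism
map00240	polar_064	Pyrimidine metabolism
map00240	polar_108	Pyrimidine metabolism
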