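surface	type	id
TGF-beta	Gene	EntrezGene:7040
Snail	Gene	EntrezGene:6615
Slug	Gene	EntrezGene:6591
Twist1	Gene	EntrezGene:7291
ZEB1	Gene	EntrezGene:6935
ZEB2	Gene	EntrezGene:9839
E-cadherin	Gene	EntrezGene:999
N-cadherin	Gene	EntrezGene:1000
Vimentin	Gene	EntrezGene:7431
SMAD2	Gene	EntrezGene:4087
SMAD3	Gene	EntrezGene:4088
SMAD4	Gene	EntrezGene:4089
STAT3	Gene	EntrezGene:6774
AKT1	Gene	EntrezGene:207
PRL-3	Gene	EntrezGene:11156
MMP-2	Gene	EntrezGene:4313
MMP-9	Gene	EntrezGene:4318
TP53	Gene	EntrezGene:7157
KRAS	Gene	EntrezGene:3845
HIF-1alpha	Gene	EntrezGene:3091
miR-181a	MicroRNA	EntrezGene:406995
miR-21	MicroRNA	EntrezGene:406991
miR-200b	MicroRNA	EntrezGene:406984
miR-200c	MicroRNA	EntrezGene:406985
miR-10b	MicroRNA	EntrezGene:406902
miR-155	MicroRNA	EntrezGene:406947
let-7a	MicroRNA	EntrezGene:406881
Metastasis	NeoplasmMetastasis	MeSH:D009362
Neoplasm metastasis	NeoplasmMetastasis	MeSH:D009362
Tumor metastasis	NeoplasmMetastasis	MeSH:D009362
Distant metastasis	NeoplasmMetastasis	MeSH:D009362
Stress fiber	Cytoskeleton	MeSH:D022682
Actin filament	Cytoskeleton	MeSH:D000199
Microfilament	Cytoskeleton	MeSH:D008841
Cytoskeleton	Cytoskeleton	MeSH:D003599
Cell aggregation	CellMovement	MeSH:D002465
Cell migration	CellMovement	MeSH:D002465
Cell motility	CellMovement	MeSH:D002465
Cell adhesion	CellAdhesion	MeSH:D002448
Cell-cell adhesion	CellAdhesion	MeSH:D002448
Liver cancer	Neoplasms	MeSH:D008113
Hepatocellular carcinoma	Neoplasms	MeSH:D006528
Breast cancer	Neoplasms	MeSH:D001943
Lung cancer	Neoplasms	MeSH:D008175
Colorectal cancer	Neoplasms	MeSH:D015179
Gastric cancer	Neoplasms	MeSH:D013274
Pancreatic cancer	Neoplasms	MeSH:D010190
Melanoma	Neoplasms	MeSH:D008545
Liver	Organ	MeSH:D008099
Lung	Organ	MeSH:D008168
Brain	Organ	MeSH:D001921
Bone	Organ	MeSH:D001842
Kidney	Organ	MeSH:D007668
Spleen	Organ	MeSH:D013154
Lymph node	Organ	MeSH:D008198
Adipose tissue	Tissues	MeSH:D000273
Connective tissue	Tissues	MeSH:D003238
Bone marrow	Tissues	MeSH:D001853
Epithelium	Tissues	MeSH:D004848
Mucosa	Tissues	MeSH:D009092
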