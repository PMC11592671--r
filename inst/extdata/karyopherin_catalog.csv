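gene,protein,role,recognition
KPNB1,Importin-beta,protein_importer,classic and non-classic NLS
IPO4,Importin-4,protein_importer,classic and non-classic NLS
IPO5,Importin-5,protein_importer,classic and non-classic NLS
IPO7,Importin-7,protein_importer,classic and non-classic NLS
IPO8,Importin-8,protein_importer,classic and non-classic NLS
IPO9,Importin-9,protein_importer,non-classic NLS
IPO11,Importin-11,protein_importer,non-classic NLS
IPO13,Importin-13,protein_importer,classic and non-classic NLS
XPO1,CRM1/Exportin-1,protein_exporter,leucine-rich NES
XPO5,Exportin-5,rna_exporter,dsRNA export
XPOT,Exportin-T,rna_exporter,amino-acylated tRNA export
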