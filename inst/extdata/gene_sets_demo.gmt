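E2F_target	demo set	gene_00001	gene_00002	gene_00003	gene_00004	gene_00005
p53_target	demo set	gene_00011	gene_00012	gene_00013	gene_00014	gene_00015
redox_metabolism	demo set	gene_00021	gene_00022	gene_00023	gene_00024	gene_00025
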