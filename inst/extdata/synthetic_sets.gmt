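cytokine_like	synthetic toy set	gene_0201	gene_0202	gene_0203	gene_0204	gene_0205	gene_0206	gene_0207	gene_0208	gene_0209	gene_0210
cell_cycle_like	synthetic toy set	gene_0251	gene_0252	gene_0253	gene_0254	gene_0255	gene_0256	gene_0257	gene_0258	gene_0259	gene_0260
housekeeping_like	synthetic toy set	gene_1001	gene_1002	gene_1003	gene_1004	gene_1005	gene_1006	gene_1007	gene_1008	gene_1009	gene_1010
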