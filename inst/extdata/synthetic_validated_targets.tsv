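mirna_id	gene_id	evidence
mir_0001	gene_0351	strong
mir_0002	gene_0352	strong
mir_0003	gene_0353	weak
mir_0004	gene_0354	strong
mir_0005	gene_0355	prediction_only
mir_0001	gene_0400	weak
mir_0002	gene_0500	strong
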