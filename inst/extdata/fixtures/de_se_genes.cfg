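# Differential-expression fixture: 2000 genes, 6 samples per group,
# negative-binomial counts (base mean 500, dispersion 0.01); 388 designed
# downregulated and 524 upregulated genes at |log2FC| = 2; 236 genes carry
# the super-enhancer association flag, 99 of them among the designed DE
# genes. The effect size is large against the null log2FC spread (~0.09),
# so the designed sets are recovered exactly for any seed.
fixture = de_se_genes
seed = 1955

n_genes = 2000
n_per_group = 6
base_mean = 500
dispersion = 0.01
n_down = 388
n_up = 524
log2fc = 2
n_se = 236
n_se_de = 99
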