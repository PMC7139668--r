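# Two-cistrome fixture emulating the MCF-7 ERalpha / NR2F2 comparison:
# 1000 NR2F2 peaks of which 900 (90%) overlap an ERalpha peak, plus
# factor-specific peaks separated by > 1 kb from the other set.
fixture = mcf7_like
seed = 20214

label_a = ERalpha
label_b = NR2F2
n_a = 2000
n_b = 1000
n_shared = 900
peak_width = 400
spacing = 3000
n_chrom = 4
chrom_len = 3000000

# fragment pile design for the signal stage (class-dependent enrichment)
frag_len = 200
frag_flank = 200
frag_mean_shared = 50
frag_mean_only = 10
frag_background = 2000
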