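# Super-enhancer / chromatin-loop fixture: 1250 mother regions of which
# 790 (63.2%) and 2500 daughter regions of which 286 (11.44%) overlap a
# peak anchored by a chromatin loop; standalone peaks populate the
# >=2 / 1 / 0 interaction strata with designed intensity ordering.
fixture = se_loops
seed = 422

n_mother = 1250
looped_mother = 790
n_daughter = 2500
looped_daughter = 286
mother_width = 2000
daughter_width = 1000
peak_width = 400
spacing = 6000
n_chrom = 8
chrom_len = 3000000

n_strata2 = 150
n_strata1 = 300
n_strata0 = 400

# fragment design: binding intensity ordered by interaction count
frag_len = 200
frag_flank = 200
frag_mean_strata2 = 60
frag_mean_strata1 = 30
frag_mean_strata0 = 10
frag_mean_se_looped = 40
frag_mean_se_silent = 15
frag_background = 1000
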