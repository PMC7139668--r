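# Motif percent-of-target fixture: two classes of 10,000 sequences of
# 100 bp; 3091 shared-class (30.91%) and 1764 only-class (17.64%)
# sequences carry one embedded GATA3 consensus; all remaining sequences
# are certified hit-free at the default scanning threshold.
fixture = motif_freq
seed = 1910

motif = GATA3
n_per_class = 10000
embed_shared = 3091
embed_only = 1764
seq_len = 100
gc = 0.41
max_retry = 1000
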