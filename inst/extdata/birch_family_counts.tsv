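# Number of colchicine-induced autotetraploid birch individuals recovered
# per full-sib family.
family	n_autotetraploid
5x3	31
5x9	22
5x11	23
6x5	23
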