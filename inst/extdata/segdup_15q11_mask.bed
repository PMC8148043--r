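chr15	22745000	22770000	BP1_flank_segdup
chr15	23270000	23295000	BP2_flank_segdup
chr15	28575000	28605000	BP3_flank_segdup
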