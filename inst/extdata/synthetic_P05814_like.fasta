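>synthetic|P05814-like|CASB_HUMAN_SYNTHETIC synthetic stand-in for the human beta-casein precursor; residues 16-30 and 190-226 are documented beta-casein fragments, the remainder is synthetic filler; NOT the UniProtKB P05814 sequence
MKVLILAFLAVALAERETIESLSSSEESITLQPVENAVLPKHQIFLQPVENAVLPKHQIF
LQPVENAVLPKHQIFLQPVENAVLPKHQIFLQPVENAVLPKHQIFLQPVENAVLPKHQIF
LQPVENAVLPKHQIFLQPVENAVLPKHQIFLQPVENAVLPKHQIFLQPVENAVLPKHQIF
LQPVENAVLAVPVQALLLNQELLLNPTHQIYPVTQPLAPVHNPISV
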