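# dwgsim read names:
#   chrom_pos1_pos2_strand1_strand2_rand1_rand2_e:e:e_e:e:e_counterhex[/end]
# Positions are the LEFTMOST nucleotide of each end; strands are 0/1.
name=dwgsim
pattern=^(?<chrom>.+)_(?<pos1>\d+)_(?<pos2>\d+)_(?<strand1>[01])_(?<strand2>[01])_[01]_[01]_\d+:\d+:\d+_\d+:\d+:\d+_(?<counter>[0-9a-fA-F]+)(?:/(?<end>[12]))?$
semantics=LEFTMOST_EACH_END
pairing=suffix
strands_default=N,N
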