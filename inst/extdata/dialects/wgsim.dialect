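# wgsim read names: chrom_pos1_pos2_err:sub:indel_err:sub:indel_counterhex[/end]
# Positions are the FIRST nucleotide of each end; wgsim emits an FR pair
# (end 1 forward at pos1, end 2 reverse whose first nucleotide is pos2).
name=wgsim
pattern=^(?<chrom>.+)_(?<pos1>\d+)_(?<pos2>\d+)_\d+:\d+:\d+_\d+:\d+:\d+_(?<counter>[0-9a-fA-F]+)(?:/(?<end>[12]))?$
semantics=FIRST_NUCLEOTIDE_EACH_END
pairing=suffix
strands_default=F,R
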