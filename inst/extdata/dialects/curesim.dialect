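# CuReSim read names (single-end): chrom_pos_counter
# The position is the LEFTMOST nucleotide; the strand is not encoded, so
# the direction is 'N' and the right coordinate is left unknown (0)
# rather than guessed. Upstream formats drift: override by editing a
# copy of this file and loading it with load_dialect_file().
name=curesim
pattern=^(?<chrom>.+)_(?<pos1>\d+)_(?<counter>\d+)$
semantics=LEFTMOST_EACH_END
pairing=file
strands_default=N,N
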