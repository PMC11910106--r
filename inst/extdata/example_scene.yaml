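# Example scene-generator configuration: an R98W-like cell with a
# fragmented mitochondrial network and 2.98-fold reporter enrichment.
enrichment: 2.98
mitoMode: fragmented
cellRadius: 7
mitoTotalLength: 120
seed: 11
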