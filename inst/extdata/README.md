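# extdata

- `mycoplasma_csb_before.tsv`: unrefined coordinates of the three synteny
  blocks flanking the M. hyorhinis HUB-1 / SK76 inversion, in the swapped-Y
  reverse-strand table dialect (x_start, x_end, y_start, y_end, strand).
- `mycoplasma_repeat_pairs_synthetic.tsv`: the four junction
  repeat spans of the same comparison combined into paired X/Y records.
  The per-sequence spans are reference coordinates; their pairing into two-sequence records is a synthetic
  construction (hence the filename), adequate for coordinate-level examples
  and tests but not a real alignment product.

Both tables are coordinate-only fixtures; the genome sequences themselves
are not distributed and must be fetched separately for a full run.
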