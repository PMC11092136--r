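Optional canonical UniProt sequences for the worked-example distances land
here as uniprot_worked_examples.fasta (see scripts/fetch_worked_examples.R;
network required). Nothing else is bundled.
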