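#!/usr/bin/env Rscript

# Downloads the canonical UniProt sequences behind the worked-example
# reference distances into inst/extdata/ (requires network access). Re-install
# the package afterwards so the file ships with it, then the worked-example
# acceptance test and `worked_example_distances()` can run offline.
#
# Usage (from the repository root):
#   Rscript scripts/fetch_worked_examples.R

library(drembed)

accessions <- c(
  # one-hot / SGT worked-example pairs
  "P35354", "Q92743", "Q9NUW8", "P02708", "O76082", "P50416",
  # remaining pairs quoted alongside them (external-embedding examples)
  "Q9Y4W6", "Q92769", "Q9UBY8", "P00492"
)

out <- file.path("inst", "extdata", "uniprot_worked_examples.fasta")
dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
fetch_uniprot_sequences(accessions, out)
cat("wrote", out, "-", length(accessions), "sequences\n")
cat("re-install the package to bundle the file (R CMD INSTALL .)\n")
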