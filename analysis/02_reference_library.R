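#!/usr/bin/env Rscript
# Stage 2: build the virtual reference tag library.
#
# The transcriptome FASTA is digested in silico at every NlaIII site
# (CATG) with at least 17 nt downstream, on both strands; tags are
# ranked from the 3' end and classified as unambiguous (one gene) or
# ambiguous (shared). With several source databases the merge step
# would reduce them by priority first; the synthetic study has one
# source, so the merge is a pass-through here.

suppressPackageStartupMessages(library(tagdge))

cfg <- read_config("results/config.yaml")
meta <- list(config = config_hash(cfg), seed = cfg$seed)

records <- read_transcript_fasta("results/data/transcriptome.fasta",
                                 sources = cfg$priority[1],
                                 priorities = 1L)
records <- merge_databases(records)
ref <- build_reference_library(records)
write_reference_library(ref, "results/reference_library.tsv", meta)

print(ref)
sense <- ref$tags[ref$tags$strand == "sense", ]
cat("Sense-strand tag occurrences:", nrow(sense), "\n")
cat("Ambiguous tag sequences:",
    ref$n_total_tags - ref$n_unambiguous_tags, "\n")
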