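#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Two tag libraries of unequal depth are drawn from a shared 2,000-gene
# transcriptome with 200 planted 8-fold genes, sequencing error, and
# adaptor / N-containing contamination, plus mitochondrial and nuclear
# genome decoys. Everything is written under results/data/ so the later
# stages consume files, exactly as they would with real sequencer
# output.

suppressPackageStartupMessages(library(tagdge))

seed <- as.integer(Sys.getenv("TAGDGE_SEED", "1"))
cfg <- default_config(seed)
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
write_config(cfg, "results/config.yaml")
meta <- list(config = config_hash(cfg), seed = seed)

truth <- synthetic_truth(
  n_genes = cfg$synthetic$n_genes, n1 = cfg$synthetic$n1,
  n2 = cfg$synthetic$n2, n_de = cfg$synthetic$n_de,
  log2fc = cfg$synthetic$log2fc, error_rate = cfg$synthetic$error_rate,
  adaptor_frac = cfg$synthetic$adaptor_frac,
  lowq_frac = cfg$synthetic$lowq_frac,
  mito_frac = cfg$synthetic$mito_frac,
  genome_frac = cfg$synthetic$genome_frac,
  abund_sdlog = cfg$synthetic$abund_sdlog,
  min_expected = cfg$synthetic$min_expected, seed = seed)
txome <- generate_transcriptome(
  cfg$synthetic$n_genes, length_range = cfg$synthetic$length_range,
  catg_sites_range = cfg$synthetic$catg_sites_range,
  shared_tag_fraction = cfg$synthetic$shared_tag_fraction, seed = seed)
genomes <- generate_genomes(cfg$synthetic$mito_length,
                            cfg$synthetic$nuclear_length, seed = seed)
libs <- simulate_libraries(truth, txome, genomes)

write_fasta(txome$sequences, "results/data/transcriptome.fasta")
write_fasta(c(MT = genomes$mito), "results/data/mito.fasta")
write_fasta(c(CHR = genomes$nuclear), "results/data/nuclear.fasta")

# raw reads as two-column tag/count tables (the compact raw-tag format)
raw_counts <- function(reads) {
  tab <- table(reads)
  data.frame(tag_seq = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}
write_report(raw_counts(libs$reads1), "results/data/raw_tags_lib1.tsv",
             meta)
write_report(raw_counts(libs$reads2), "results/data/raw_tags_lib2.tsv",
             meta)
write_report(libs$ledger, "results/data/planted_ledger.tsv", meta)

# the truth ledger: planted abundances and fold changes per gene
truth_tab <- data.frame(
  gene_id = truth$genes, abundance = truth$abundance,
  freq_lib1 = truth$p1, freq_lib2 = truth$p2,
  planted_de = truth$genes %in% truth$de_genes,
  log2fc_realized = truth$log2fc_realized, stringsAsFactors = FALSE)
write_report(truth_tab, "results/data/truth.tsv", meta)

cat("Simulated", length(libs$reads1), "and", length(libs$reads2),
    "raw tags for the two libraries\n")
cat("Planted", length(truth$de_genes), "genes at |log2FC| =",
    truth$log2fc_planted, "\n")
cat("Contamination fractions: adaptor", truth$adaptor_frac,
    "low-quality", truth$lowq_frac, "\n")
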