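#!/usr/bin/env Rscript
# Stage 7: qPCR validation math.
#
# A panel of the top significant genes is "assayed" on a synthetic Ct
# table (three animals per breed, triplicate technical replicates,
# RPS20 reference) whose planted ratios equal the DGE TPM ratios; the
# 2^-ddCt estimates and Welch t-tests are then compared side by side
# with the DGE fold changes.

suppressPackageStartupMessages(library(tagdge))

cfg <- read_config("results/config.yaml")
meta <- list(config = config_hash(cfg), seed = cfg$seed)

de <- read_report("results/de_table.tsv")
de$significant <- de$significant == "TRUE" | de$significant == TRUE
sig <- de$gene_id[de$significant]
panel <- head(sig, cfg$qpcr$n_validation_genes)
stopifnot(length(panel) >= 1)

ratios <- setNames(de$tpm_a[match(panel, de$gene_id)] /
                     de$tpm_b[match(panel, de$gene_id)], panel)
ct <- generate_ct_table(ratios, groups = c("lib1", "lib2"),
                        n_animals = cfg$qpcr$n_animals,
                        n_tech = cfg$qpcr$n_tech,
                        reference = cfg$qpcr$reference, seed = cfg$seed)
write_report(ct, "results/data/ct_table.tsv", meta)

qp <- qpcr_panel(ct, panel, reference = cfg$qpcr$reference,
                 group_a = "lib1", group_b = "lib2")
write_report(qp, "results/qpcr_validation.tsv", meta)
conc <- concordance_table(qp, de)
write_report(conc, "results/qpcr_concordance.tsv", meta)

cat("qPCR panel of", length(panel), "genes, reference",
    cfg$qpcr$reference, "\n")
print(conc[, c("gene_id", "qpcr_ratio", "dge_ratio", "qpcr_p", "dge_fdr")],
      row.names = FALSE)
agree <- sign(conc$qpcr_log2) == sign(conc$dge_log2)
cat(sprintf("Direction concordance with DGE: %d/%d\n", sum(agree),
            length(agree)))
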