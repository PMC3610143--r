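test_that("generated transcripts carry exactly the requested CATG sites", {
  tx <- generate_transcriptome(30, catg_sites_range = c(1, 4), seed = 2)
  for (g in seq_len(30)) {
    d <- digest_transcript(tx$sequences[g], tx$metadata$gene_id[g])
    sense <- d[d$strand == "sense", ]
    expect_equal(nrow(sense), tx$metadata$n_sites[g])
    # the declared rank-1 tag is the 3'-most sense tag
    expect_equal(sense$tag_seq[sense$position_rank == 1L],
                 tx$metadata$rank1_tag[g])
  }
  expect_error(generate_transcriptome(5, length_range = c(10, 20),
                                      catg_sites_range = c(3, 3)),
               "too short")
})

test_that("without shared tags every sense reference tag is unambiguous", {
  tx <- generate_transcriptome(100, shared_tag_fraction = 0, seed = 6)
  lib <- build_reference_library(
    transcript_records(names(tx$sequences), tx$sequences))
  sense <- lib$tags[lib$tags$strand == "sense", ]
  genes_per <- tapply(sense$gene_id, sense$tag_seq,
                      function(g) length(unique(g)))
  expect_true(all(genes_per == 1L))

  # a requested shared fraction produces ambiguous sense tags
  tx2 <- generate_transcriptome(100, shared_tag_fraction = 0.2, seed = 6)
  lib2 <- build_reference_library(
    transcript_records(names(tx2$sequences), tx2$sequences))
  sense2 <- lib2$tags[lib2$tags$strand == "sense", ]
  genes_per2 <- tapply(sense2$gene_id, sense2$tag_seq,
                       function(g) length(unique(g)))
  expect_gt(sum(genes_per2 > 1L), 0)
})

test_that("generators are deterministic per seed", {
  t1 <- generate_transcriptome(20, seed = 9)
  t2 <- generate_transcriptome(20, seed = 9)
  expect_identical(t1$sequences, t2$sequences)
  expect_false(identical(
    t1$sequences, generate_transcriptome(20, seed = 10)$sequences))

  a1 <- generate_annotations(paste0("G", 1:50), seed = 4)
  a2 <- generate_annotations(paste0("G", 1:50), seed = 4)
  expect_identical(a1$membership, a2$membership)

  c1 <- generate_ct_table(c(GX = 2), seed = 3)
  c2 <- generate_ct_table(c(GX = 2), seed = 3)
  expect_identical(c1, c2)

  tr1 <- synthetic_truth(seed = 5)
  tr2 <- synthetic_truth(seed = 5)
  expect_identical(tr1$p1, tr2$p1)
  expect_identical(tr1$de_genes, tr2$de_genes)
})

test_that("a noise-free single-gene library collapses to that gene's tag", {
  truth <- synthetic_truth(n_genes = 1, n1 = 500, n2 = 500, n_de = 0,
                           error_rate = 0, adaptor_frac = 0,
                           lowq_frac = 0, mito_frac = 0, genome_frac = 0,
                           abund_sdlog = 0, min_expected = 1, seed = 3)
  tx <- generate_transcriptome(1, seed = 3)
  libs <- simulate_libraries(truth, tx)
  expect_equal(unique(libs$reads1), tx$metadata$rank1_tag)
  expect_equal(length(libs$reads1), 500L)
  res <- filter_raw_tags(libs$reads1)
  expect_equal(res$clean$n_unique, 1L)
  expect_equal(res$clean$total_clean, 500L)
})

test_that("planted contamination fractions reappear in the filter ledger", {
  truth <- synthetic_truth(n1 = 50000, n2 = 50000, adaptor_frac = 0.01,
                           lowq_frac = 0.02, mito_frac = 0,
                           genome_frac = 0, error_rate = 0, seed = 8)
  tx <- generate_transcriptome(2000, seed = 8)
  libs <- simulate_libraries(truth, tx)
  res <- filter_raw_tags(libs$reads1,
                         adaptor_seqs = "TCGTATGCCGTCTTCTGCTTG")
  n <- truth$n1
  for (pair in list(c(res$ledger$n_adaptor, 0.01),
                    c(res$ledger$n_low_quality, 0.02))) {
    se <- sqrt(n * pair[2] * (1 - pair[2]))
    expect_lt(abs(pair[1] - n * pair[2]), 3 * se + 1)
  }
  # the ledger entry agrees with the simulator's own truth ledger
  led <- libs$ledger[libs$ledger$library == "lib1", ]
  expect_equal(res$ledger$n_adaptor,
               led$n_reads[led$category == "adaptor"])
  expect_equal(res$ledger$n_low_quality,
               led$n_reads[led$category == "lowq"])
})

test_that("an error-free simulated library maps entirely to genes", {
  truth <- synthetic_truth(n_genes = 300, n1 = 30000, n2 = 30000,
                           n_de = 20, error_rate = 0, adaptor_frac = 0,
                           lowq_frac = 0, mito_frac = 0, genome_frac = 0,
                           min_expected = 10, seed = 12)
  tx <- generate_transcriptome(300, seed = 12)
  lib <- build_reference_library(
    transcript_records(names(tx$sequences), tx$sequences))
  filt <- filter_raw_tags(simulate_libraries(truth, tx)$reads1)
  res <- map_library(filt$clean, lib)
  expect_equal(res$summary$counts[["Tags Mapped to Gene"]],
               filt$clean$total_clean)
  expect_equal(res$summary$counts[["Unknown Tags"]], 0)
  expect_equal(res$summary$pct$total_pct[1], 100)
})

test_that("a planted term at odds ratio 1 shows no systematic enrichment", {
  set.seed(99)
  genes <- paste0("G", 1:400)
  de <- paste0("G", 1:50)
  qs <- sapply(1:12, function(s) {
    ann <- generate_annotations(genes, n_terms = 10,
                                term_size_range = c(20, 40),
                                enriched = list(genes = de, size = 30,
                                                odds_ratio = 1),
                                seed = s)
    res <- hypergeom_enrich(de, genes, ann$membership)
    res$p_value[res$term_id == "T_PLANTED"]
  })
  # null p-values should not pile up near zero
  expect_gt(median(qs), 0.1)
  expect_lt(mean(qs < 0.05), 0.35)

  # a term containing every gene is never significant
  ann_all <- data.frame(term_id = "T", gene_id = genes)
  expect_false(hypergeom_enrich(de, genes, ann_all)$significant)
})
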