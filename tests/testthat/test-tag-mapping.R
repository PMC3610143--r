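ref_fixture <- function() {
  # G1: one unique sense tag; G2: unique sense tag; G1/G2 share one
  # ambiguous tag; G3: antisense-only tag
  t1 <- paste0("CATG", strrep("A", 17))
  t2 <- paste0("CATG", strrep("C", 17))
  sh <- paste0("CATG", strrep("G", 17))
  anti <- paste0("CATG", paste(rep(c("A", "C"), length.out = 17),
                               collapse = ""))
  tags <- data.frame(
    tag_seq = c(t1, t2, sh, sh, anti),
    gene_id = c("G1", "G2", "G1", "G2", "G3"),
    strand = c("sense", "sense", "sense", "sense", "antisense"),
    position_rank = c(1L, 1L, 2L, 2L, 1L),
    offset = c(0L, 0L, 30L, 30L, 5L),
    source = "unigene",
    ambiguous = c(FALSE, FALSE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  structure(list(tags = tags, n_total_tags = 4L, n_unambiguous_tags = 3L),
            class = "ref_tag_library")
}

test_that("single-tag mapping follows the tier and precedence rules", {
  lib <- ref_fixture()
  t1 <- paste0("CATG", strrep("A", 17))
  sh <- paste0("CATG", strrep("G", 17))
  anti <- paste0("CATG", paste(rep(c("A", "C"), length.out = 17),
                               collapse = ""))

  exact <- map_tag(t1, lib)
  expect_equal(exact$category, "gene_unambiguous")
  expect_equal(exact$gene_id, "G1")
  expect_equal(exact$mismatches, 0L)
  expect_equal(exact$position_rank, 1L)

  # one substitution away from G1's tag only
  mm <- map_tag(paste0("CATG", "T", strrep("A", 16)), lib)
  expect_equal(mm$category, "gene_unambiguous")
  expect_equal(mm$gene_id, "G1")
  expect_equal(mm$mismatches, 1L)

  # exact hit on a two-gene tag is ambiguous
  amb <- map_tag(sh, lib)
  expect_equal(amb$category, "gene_ambiguous")

  # antisense-only hit
  as <- map_tag(anti, lib)
  expect_equal(as$category, "antisense_gene")
  expect_equal(as$gene_id, "G3")

  # no hit within one mismatch
  far <- map_tag(paste0("CATG", paste(rep(c("T", "G"), length.out = 17),
                                      collapse = "")), lib)
  expect_equal(far$category, "unknown")

  expect_error(map_tag("CATGAA", lib), "21")
})

test_that("exact matches beat mismatch matches, and sense beats antisense", {
  t_sense <- paste0("CATG", strrep("A", 17))
  t_anti <- paste0("CATG", "C", strrep("A", 16))  # 1 mismatch from t_sense
  tags <- data.frame(tag_seq = c(t_sense, t_anti),
                     gene_id = c("G1", "G2"),
                     strand = c("sense", "antisense"),
                     position_rank = c(1L, 1L), offset = c(0L, 0L),
                     source = "u", ambiguous = FALSE,
                     stringsAsFactors = FALSE)
  lib <- structure(list(tags = tags, n_total_tags = 2L,
                        n_unambiguous_tags = 2L),
                   class = "ref_tag_library")
  # the query matches G1 exactly and G2 at distance 1: exact tier wins
  hit <- map_tag(t_sense, lib)
  expect_equal(hit$gene_id, "G1")
  expect_equal(hit$mismatches, 0L)

  # equal tier: a query 1 away from both lands on the sense gene
  q <- paste0("CATG", "G", strrep("A", 16))
  hit2 <- map_tag(q, lib)
  expect_equal(hit2$category, "gene_unambiguous")
  expect_equal(hit2$gene_id, "G1")
  expect_equal(hit2$mismatches, 1L)
})

test_that("mapping agrees with an exhaustive Hamming scan on random instances", {
  set.seed(77)
  for (rep_i in 1:5) {
    n_ref <- sample(50:200, 1)
    tags <- data.frame(
      tag_seq = unique(replicate(n_ref, rand_tag())),
      stringsAsFactors = FALSE)
    tags$gene_id <- paste0("G", sample(1:40, nrow(tags), replace = TRUE))
    tags$strand <- sample(c("sense", "antisense"), nrow(tags), TRUE,
                          prob = c(0.8, 0.2))
    tags$position_rank <- 1L
    tags$offset <- 0L
    tags$source <- "u"
    tags$ambiguous <- FALSE
    lib <- structure(list(tags = tags, n_total_tags = nrow(tags),
                          n_unambiguous_tags = 0L),
                     class = "ref_tag_library")
    queries <- c(sample(tags$tag_seq, 10),
                 vapply(sample(tags$tag_seq, 10), function(t) {
                   p <- sample(21, 1)
                   substr(t, p, p) <- sample(setdiff(BASES,
                                                     substr(t, p, p)), 1)
                   t
                 }, character(1), USE.NAMES = FALSE),
                 replicate(10, rand_tag()))
    for (q in queries) {
      got <- map_tag(q, lib)
      want <- brute_map(q, tags)
      expect_equal(got$category, want$category, info = q)
      if (want$category %in% c("gene_unambiguous", "antisense_gene")) {
        expect_equal(got$gene_id, want$gene_id, info = q)
        expect_equal(got$mismatches, want$mismatches, info = q)
      }
    }
  }
})

test_that("the library cascade partitions every clean tag exactly once", {
  lib <- ref_fixture()
  t1 <- paste0("CATG", strrep("A", 17))
  t2 <- paste0("CATG", strrep("C", 17))
  sh <- paste0("CATG", strrep("G", 17))
  anti <- paste0("CATG", paste(rep(c("A", "C"), length.out = 17),
                               collapse = ""))
  mito_tag <- rand_tag()
  geno_tag <- rand_tag()
  unknown_tag <- paste0("CATG", paste(rep(c("T", "G"), length.out = 17),
                                      collapse = ""))
  mito <- paste0(rand_seq(40), mito_tag, rand_seq(40))
  genome <- paste0(rand_seq(60), geno_tag, rand_seq(60))

  clean <- clean_tag_library(data.frame(
    tag_seq = c(t1, t2, sh, anti, mito_tag, geno_tag, unknown_tag),
    count = c(10L, 6L, 4L, 7L, 3L, 5L, 2L)))
  res <- map_library(clean, lib, mito = mito, genome = genome,
                     max_mismatch = 0L)
  ann <- res$annotations
  expect_equal(sort(unique(ann$category)),
               sort(c("gene_unambiguous", "gene_ambiguous",
                      "antisense_gene", "mitochondrion", "genome",
                      "unknown")))
  # category totals partition the clean totals (the gene row subsumes
  # the unambiguous row, so drop the latter before summing)
  tot <- res$summary$counts
  expect_equal(sum(tot) - tot[["Unambiguous Tags Mapped to Gene"]],
               clean$total_clean)
  by_cat <- tapply(ann$count, ann$category, sum)
  expect_equal(sum(by_cat), clean$total_clean)
  expect_equal(sum(tapply(ann$tag_seq, ann$category, length)),
               clean$n_unique)

  # gene counts use unambiguous sense tags only
  gc <- setNames(res$gene_counts$count, res$gene_counts$gene_id)
  expect_equal(gc[["G1"]], 10L)
  expect_equal(gc[["G2"]], 6L)
  expect_false("G3" %in% names(gc))

  # antisense observations are tallied separately
  ar <- antisense_report(ann)
  expect_equal(ar$gene_id, "G3")
  expect_equal(ar$total_tags, 7L)
  expect_equal(ar$unique_tags, 1L)

  # the planted genomic 21-mer cascades to the genome category
  expect_equal(ann$category[ann$tag_seq == geno_tag], "genome")
  expect_equal(ann$category[ann$tag_seq == mito_tag], "mitochondrion")
  expect_equal(ann$category[ann$tag_seq == unknown_tag], "unknown")
})

test_that("full reference coverage leaves no unknown tags", {
  set.seed(31)
  recs <- transcript_records(sprintf("G%02d", 1:10),
                             replicate(10, rand_seq(150)))
  lib <- build_reference_library(recs)
  sense <- lib$tags[lib$tags$strand == "sense" & !lib$tags$ambiguous, ]
  picked <- sense[!duplicated(sense$gene_id), ]
  clean <- clean_tag_library(data.frame(tag_seq = picked$tag_seq,
                                        count = rep(5L, nrow(picked))))
  res <- map_library(clean, lib)
  expect_equal(res$summary$counts[["Unknown Tags"]], 0)
  expect_equal(res$summary$counts[["Tags Mapped to Gene"]],
               clean$total_clean)
  expect_equal(res$summary$pct$total_pct[1], 100)
})

test_that("gene counts are invariant to the order of the clean tags", {
  lib <- ref_fixture()
  df <- data.frame(tag_seq = c(paste0("CATG", strrep("A", 17)),
                               paste0("CATG", strrep("C", 17))),
                   count = c(9L, 4L))
  r1 <- map_library(clean_tag_library(df), lib)
  r2 <- map_library(clean_tag_library(df[2:1, ]), lib)
  expect_equal(r1$gene_counts, r2$gene_counts)
})

test_that("the position profile weights ranks by copy number", {
  ann <- data.frame(tag_seq = c("a", "b", "c"),
                    category = "gene_unambiguous",
                    gene_id = c("G1", "G2", "G3"),
                    strand = "sense", mismatches = 0L,
                    position_rank = c(1L, 1L, 2L),
                    count = c(10L, 5L, 5L),
                    stringsAsFactors = FALSE)
  prof <- tag_position_profile(ann)
  expect_equal(prof$histogram$total_tags, c(15L, 5L))
  expect_equal(prof$fraction_rank1, 0.75)

  all1 <- tag_position_profile(ann[ann$position_rank == 1L, ])
  expect_equal(all1$fraction_rank1, 1.0)

  none <- tag_position_profile(ann[0, ])
  expect_equal(nrow(none$histogram), 0L)
  expect_true(is.na(none$fraction_rank1))
})

test_that("tags sampled from 3'-most sites concentrate the profile at rank 1", {
  set.seed(19)
  tx <- generate_transcriptome(40, catg_sites_range = c(2, 3), seed = 19)
  recs <- transcript_records(names(tx$sequences), tx$sequences)
  lib <- build_reference_library(recs)
  clean <- clean_tag_library(data.frame(tag_seq = tx$metadata$rank1_tag,
                                        count = rep(10L, 40)))
  res <- map_library(clean, lib)
  prof <- tag_position_profile(res$annotations)
  expect_gt(prof$fraction_rank1, 0.95)
})
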