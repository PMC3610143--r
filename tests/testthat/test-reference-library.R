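test_that("digestion handles the basic site geometries", {
  # no recognition site on either strand
  expect_equal(nrow(digest_transcript(strrep("T", 24))), 0L)

  # one sense site with a full 17 nt downstream; the antisense site on
  # the reverse complement is truncated and yields nothing
  d <- digest_transcript("AACATGAAAAAAAAAAAAAAAAAGG", "g1")
  expect_equal(nrow(d), 1L)
  expect_equal(d$tag_seq, paste0("CATG", strrep("A", 17)))
  expect_equal(d$strand, "sense")
  expect_equal(d$position_rank, 1L)
  expect_equal(d$offset, 2L)

  # two sense sites: the downstream one gets rank 1
  s <- paste0("CATG", strrep("A", 17), "CATG", strrep("C", 17))
  d2 <- digest_transcript(s, "g1")
  sense <- d2[d2$strand == "sense", ]
  expect_equal(nrow(sense), 2L)
  expect_equal(sense$position_rank[order(sense$offset)], c(2L, 1L))

  # a truncated 3' site yields no tag rather than a padded one
  d3 <- digest_transcript(paste0(strrep("G", 30), "CATG", strrep("A", 5)))
  expect_equal(nrow(d3[d3$strand == "sense", ]), 0L)

  # tags containing N are discarded
  d4 <- digest_transcript(paste0("CATG", strrep("A", 8), "N",
                                 strrep("A", 8)))
  expect_equal(nrow(d4), 0L)

  expect_error(digest_transcript("CATGXX"), "non-nucleotide")
})

test_that("digestion agrees with an exhaustive window scan on random sequences", {
  set.seed(42)
  for (i in 1:60) {
    L <- sample(10:200, 1)
    s <- rand_seq(L)
    got <- digest_transcript(s, "g")
    want <- brute_digest(s, "g")
    key <- function(df) df[order(df$strand, df$offset), , drop = FALSE]
    expect_equal(unname(as.list(key(got))), unname(as.list(key(want))),
                 info = paste("sequence:", s))
  }
})

test_that("digesting the reverse complement swaps the strand sets exactly", {
  set.seed(7)
  for (i in 1:20) {
    s <- rand_seq(sample(30:150, 1))
    a <- digest_transcript(s, "g")
    b <- digest_transcript(brute_revcomp(s), "g")
    key <- function(df, strand) {
      sub <- df[df$strand == strand, c("tag_seq", "position_rank", "offset")]
      sub[order(sub$offset), , drop = FALSE]
    }
    expect_equal(unname(as.list(key(a, "sense"))),
                 unname(as.list(key(b, "antisense"))))
    expect_equal(unname(as.list(key(a, "antisense"))),
                 unname(as.list(key(b, "sense"))))
  }
})

test_that("database merging follows source priority with a tie warning", {
  hi <- transcript_records("G1", paste0("CATG", strrep("A", 17)),
                           source = "unigene", priority = 1L)
  lo <- transcript_records(c("G1", "G2"),
                           c(paste0("CATG", strrep("C", 17)),
                             paste0("CATG", strrep("G", 17))),
                           source = "tc", priority = 3L)
  m <- merge_databases(rbind(lo, hi))
  expect_equal(sort(m$gene_id), c("G1", "G2"))
  expect_equal(m$source[m$gene_id == "G1"], "unigene")

  # disjoint gene sets pass through untouched
  m2 <- merge_databases(rbind(hi, lo[lo$gene_id == "G2", ]))
  expect_equal(nrow(m2), 2L)

  # equal-priority duplicate: first occurrence kept, warning emitted
  dup <- transcript_records(c("G1", "G1"),
                            c(paste0("CATG", strrep("A", 17)),
                              paste0("CATG", strrep("T", 17))),
                            source = "unigene", priority = 1L)
  expect_warning(m3 <- merge_databases(dup), "equal priority")
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$sequence, paste0("CATG", strrep("A", 17)))

  # cross-reference table maps source ids to one canonical gene
  xref <- data.frame(source_id = c("NM_1", "ENS_1"),
                     canonical_id = c("G1", "G1"))
  both <- rbind(
    transcript_records("NM_1", paste0("CATG", strrep("A", 17)),
                       source = "unigene", priority = 1L),
    transcript_records("ENS_1", paste0("CATG", strrep("C", 17)),
                       source = "cdna", priority = 2L))
  m4 <- merge_databases(both, xref)
  expect_equal(m4$gene_id, "G1")
  expect_equal(m4$priority, 1L)

  expect_equal(nrow(merge_databases(hi[0, ])), 0L)
})

test_that("reference library groups tags and classifies ambiguity", {
  shared <- paste0("CATG", strrep("A", 17))
  recs <- transcript_records(
    c("G1", "G2"),
    c(paste0("TT", shared), paste0("GG", shared, "CC")))
  lib <- build_reference_library(recs)
  row <- lib$tags[lib$tags$tag_seq == shared, ]
  expect_true(all(row$ambiguous))
  expect_lt(lib$n_unambiguous_tags, lib$n_total_tags)

  # the same tag at two positions of one gene stays unambiguous, with
  # both positions recorded
  rep2 <- paste0(shared, "GG", shared)
  lib2 <- build_reference_library(transcript_records("G1", rep2))
  rows <- lib2$tags[lib2$tags$tag_seq == shared, ]
  expect_equal(nrow(rows), 2L)
  expect_false(any(rows$ambiguous))
  expect_equal(sort(rows$offset), c(0L, 23L))

  empty <- build_reference_library(transcript_records(character(0),
                                                      character(0)))
  expect_equal(empty$n_total_tags, 0L)
  expect_equal(empty$n_unambiguous_tags, 0L)
})

test_that("unambiguous count equals the single-gene entries on random libraries", {
  set.seed(11)
  recs <- transcript_records(sprintf("G%02d", 1:15),
                             replicate(15, rand_seq(120)))
  lib <- build_reference_library(recs)
  genes_per <- tapply(lib$tags$gene_id, lib$tags$tag_seq,
                      function(g) length(unique(g)))
  expect_equal(lib$n_unambiguous_tags, sum(genes_per == 1L))
  expect_equal(lib$n_total_tags, length(genes_per))
  expect_lte(lib$n_unambiguous_tags, lib$n_total_tags)
})

test_that("a reference library round-trips through its TSV form", {
  set.seed(3)
  recs <- transcript_records(c("G1", "G2"),
                             c(rand_seq(100), rand_seq(100)))
  lib <- build_reference_library(recs)
  f <- tempfile(fileext = ".tsv")
  write_reference_library(lib, f, meta = list(config = "abc", seed = 1))
  back <- read_reference_library(f)
  expect_equal(back$n_total_tags, lib$n_total_tags)
  expect_equal(back$n_unambiguous_tags, lib$n_unambiguous_tags)
  expect_equal(back$tags$tag_seq, lib$tags$tag_seq)
  expect_true(startsWith(readLines(f, n = 1), "## config=abc"))
})
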