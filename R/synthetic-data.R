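# Synthetic study generator: a transcriptome with controlled NlaIII
# sites, mitochondrial/nuclear genome decoys, two-condition tag
# libraries with planted fold changes and contamination, term
# annotations and Ct tables — all driven by one seed and recorded in a
# truth ledger.

DEFAULT_ADAPTOR <- "TCGTATGCCGTCTTCTGCTTG"

rand_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a random chunk free of the CATG anchor
catg_free_chunk <- function(n) {
  s <- rand_bases(n)
  while (grepl(ANCHOR, s, fixed = TRUE)) {
    s <- sub(ANCHOR, "CATT", s, fixed = TRUE)
  }
  s
}

#' Planted truth for a two-library simulation
#'
#' Defines the study conditions: per-gene base abundances (log-normal, so
#' a small minority of tags dominates the totals), a planted set of
#' fold-changed genes chosen among genes deep enough to be testable,
#' library depths with the two-library depth asymmetry, and
#' contamination/error rates. Everything downstream derives from this
#' object and its seed.
#'
#' @param n_genes number of genes (default 2000).
#' @param n1,n2 raw library depths; defaults 200000 and 319000 keep the
#'   unequal-depth ratio of about 0.63 between the two libraries.
#' @param n_de number of planted fold-changed genes (default 200), half
#'   up- and half down-regulated in library 1.
#' @param log2fc planted |log2 fold change| (default 3, i.e. 8-fold).
#' @param error_rate per-base substitution error rate (default 0.001).
#' @param adaptor_frac,lowq_frac,mito_frac,genome_frac fractions of raw
#'   reads that are adaptor contamination, N-containing reads,
#'   mitochondrial 21-mers and intergenic genomic 21-mers.
#' @param abund_sdlog sdlog of the log-normal abundance distribution.
#' @param min_expected planted genes are drawn only from genes whose
#'   expected baseline count in the shallower library is at least this
#'   (default 25), so planted effects are testable at desk scale.
#' @param seed integer seed; all downstream randomness derives from it.
#' @return object of class `synthetic_truth`: the arguments plus the
#'   per-library gene frequency vectors `p1`, `p2`, the planted gene ids
#'   (`de_genes`, `de_direction`) and realized per-gene log2 fold
#'   changes `log2fc_realized` (after renormalisation).
#' @export
synthetic_truth <- function(n_genes = 2000, n1 = 200000, n2 = 319000,
                            n_de = 200, log2fc = 3, error_rate = 0.001,
                            adaptor_frac = 0.002, lowq_frac = 0.005,
                            mito_frac = 0.0005, genome_frac = 0.005,
                            abund_sdlog = 1.5, min_expected = 25,
                            seed = 1L) {
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  ab <- stats::rlnorm(n_genes, meanlog = 0, sdlog = abund_sdlog)
  ab <- ab / sum(ab)
  signal_frac <- 1 - adaptor_frac - lowq_frac - mito_frac - genome_frac
  eligible <- which(ab * min(n1, n2) * signal_frac >= min_expected)
  if (length(eligible) < n_de) {
    stop("only ", length(eligible), " genes reach the minimum expected ",
         "count; lower n_de or min_expected")
  }
  de_idx <- sort(sample(eligible, n_de))
  dir <- rep_len(c("up_in_1", "up_in_2"), n_de)
  mult1 <- rep(1, n_genes)
  mult2 <- rep(1, n_genes)
  mult1[de_idx[dir == "up_in_1"]] <- 2^log2fc
  mult2[de_idx[dir == "up_in_2"]] <- 2^log2fc
  p1 <- ab * mult1; p1 <- p1 / sum(p1)
  p2 <- ab * mult2; p2 <- p2 / sum(p2)
  structure(list(genes = genes, abundance = ab, p1 = p1, p2 = p2,
                 de_genes = genes[de_idx], de_direction = dir,
                 log2fc_planted = log2fc,
                 log2fc_realized = log2(p1 / p2),
                 n1 = n1, n2 = n2, error_rate = error_rate,
                 adaptor_frac = adaptor_frac, lowq_frac = lowq_frac,
                 mito_frac = mito_frac, genome_frac = genome_frac,
                 signal_frac = signal_frac, min_expected = min_expected,
                 seed = seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic truth:", length(x$genes), "genes;",
      length(x$de_genes), "planted at |log2FC| =", x$log2fc_planted,
      "; depths", x$n1, "/", x$n2, "; seed", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic transcriptome with controlled NlaIII sites
#'
#' Each transcript is assembled from CATG-free backbone chunks with a
#' requested number of planted CATG + 17 nt sites, each with at least
#' 17 nt downstream, so the in-silico digest of the sense strand yields
#' exactly that many tags. The 17-mers are unique across genes unless a
#' shared-tag fraction is requested (to exercise reference ambiguity).
#'
#' @param n_genes number of transcripts.
#' @param length_range min/max backbone padding budget per transcript.
#' @param catg_sites_range min/max planted CATG sites per transcript.
#' @param shared_tag_fraction fraction of genes whose 3'-most tag is
#'   copied from another gene (default 0).
#' @param seed integer seed.
#' @return list with `sequences` (named character vector), `metadata`
#'   (data.frame gene_id, length, n_sites, rank1_tag) and `seed`.
#' @export
generate_transcriptome <- function(n_genes, length_range = c(200, 600),
                                   catg_sites_range = c(1, 3),
                                   shared_tag_fraction = 0, seed = 1L) {
  stopifnot(n_genes >= 1, all(length_range > 0), all(catg_sites_range >= 1))
  if (length_range[2] < catg_sites_range[2] * (TAG_LEN + 2L) + 10L) {
    stop("length_range too short for the requested number of CATG sites")
  }
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  n_sites <- sample(seq(catg_sites_range[1], catg_sites_range[2]),
                    n_genes, replace = TRUE)
  total_sites <- sum(n_sites)
  # unique, CATG-free 17-mers for all sites
  seventeens <- character(0)
  while (length(seventeens) < total_sites) {
    cand <- vapply(seq_len(total_sites - length(seventeens) + 20L),
                   function(i) rand_bases(DOWNSTREAM_LEN), character(1))
    cand <- cand[!grepl(ANCHOR, cand, fixed = TRUE)]
    seventeens <- unique(c(seventeens, cand))
  }
  seventeens <- seventeens[seq_len(total_sites)]
  site_of_gene <- split(seq_len(total_sites), rep(seq_len(n_genes), n_sites))

  if (shared_tag_fraction > 0 && n_genes > 1L) {
    n_shared <- round(shared_tag_fraction * n_genes)
    recipients <- sample(seq_len(n_genes), n_shared)
    for (g in recipients) {
      donor <- sample(setdiff(seq_len(n_genes), g), 1L)
      # copy the donor's 3'-most site into the recipient's 3'-most site
      seventeens[utils::tail(site_of_gene[[g]], 1L)] <-
        seventeens[utils::tail(site_of_gene[[donor]], 1L)]
    }
  }

  sequences <- character(n_genes)
  rank1 <- character(n_genes)
  for (g in seq_len(n_genes)) {
    k <- n_sites[g]
    pad <- sample(seq(length_range[1], length_range[2]), 1L)
    chunk_len <- pmax(3L, diff(floor(seq(0, pad, length.out = k + 2L))))
    tags17 <- seventeens[site_of_gene[[g]]]
    parts <- character(0)
    parts <- c(parts, catg_free_chunk(chunk_len[1]))
    for (s in seq_len(k)) {
      # "TT" guard prevents a CATG spanning the tag/backbone junction
      parts <- c(parts, ANCHOR, tags17[s], "TT",
                 catg_free_chunk(chunk_len[s + 1L]))
    }
    sequences[g] <- paste(parts, collapse = "")
    rank1[g] <- paste0(ANCHOR, tags17[k])
  }
  names(sequences) <- genes
  list(sequences = sequences,
       metadata = data.frame(gene_id = genes,
                             length = nchar(sequences),
                             n_sites = n_sites,
                             rank1_tag = rank1,
                             stringsAsFactors = FALSE),
       seed = seed)
}

#' Generate mitochondrial and nuclear genome decoys
#'
#' Random sequences used by the mapping cascade; tags sampled from them
#' stand in for mitochondrial transcripts and unannotated (novel)
#' transcription.
#'
#' @param mito_length,nuclear_length sequence lengths.
#' @param seed integer seed.
#' @return list with `mito` and `nuclear` (single strings) and `seed`.
#' @export
generate_genomes <- function(mito_length = 8000, nuclear_length = 40000,
                             seed = 1L) {
  set.seed(seed + 101L)
  list(mito = rand_bases(mito_length),
       nuclear = rand_bases(nuclear_length),
       seed = seed)
}

# sample n reads from a genome: a small pool of distinct 21-mers (so
# they survive the singleton filter), excluding reference tag sequences
sample_genome_reads <- function(n, genome_seq, exclude, pool_size = 15L) {
  if (n == 0L) return(character(0))
  L <- nchar(genome_seq)
  pool <- character(0)
  tries <- 0L
  while (length(pool) < pool_size && tries < 200L) {
    pos <- sample.int(L - TAG_LEN + 1L, pool_size)
    cand <- substring(genome_seq, pos, pos + TAG_LEN - 1L)
    pool <- unique(c(pool, setdiff(cand, exclude)))
    tries <- tries + 1L
  }
  pool <- utils::head(pool, pool_size)
  sample(pool, n, replace = TRUE)
}

# apply per-base substitution errors to reads; the per-read error count
# is exactly Binomial(21, rate), sampled via its truncated quantile
apply_sequencing_errors <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  p_any <- 1 - (1 - rate)^TAG_LEN
  flagged <- which(stats::runif(length(reads)) < p_any)
  if (!length(flagged)) return(reads)
  p0 <- stats::pbinom(0, TAG_LEN, rate)
  k <- stats::qbinom(stats::runif(length(flagged), p0, 1), TAG_LEN, rate)
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(flagged)) {
    r <- reads[flagged[i]]
    for (pos in sample.int(TAG_LEN, k[i])) {
      cur <- substring(r, pos, pos)
      substring(r, pos, pos) <- sample(setdiff(bases, cur), 1L)
    }
    reads[flagged[i]] <- r
  }
  reads
}

#' Simulate the two raw tag libraries
#'
#' Draws each library's reads multinomially: signal reads come from each
#' gene's 3'-most (rank-1) sense tag under the truth's per-library gene
#' frequencies, with per-base substitution errors; contamination reads
#' are adaptor copies and N-containing reads; decoy reads are 21-mers
#' from the mitochondrial and nuclear genomes. The returned ledger
#' records every planted per-category count.
#'
#' @param truth a [synthetic_truth()].
#' @param transcriptome from [generate_transcriptome()]; must cover the
#'   truth's genes.
#' @param genomes optional list from [generate_genomes()]; without it the
#'   mito/genome read fractions are reallocated to signal.
#' @param exclude_tags tag sequences the genome decoy reads must avoid
#'   (defaults to the transcriptome's rank-1 tags).
#' @return list with `reads1`, `reads2` (character vectors in shuffled
#'   order) and `ledger` (data.frame: library, category, n_reads).
#' @export
simulate_libraries <- function(truth, transcriptome, genomes = NULL,
                               exclude_tags = transcriptome$metadata$rank1_tag) {
  stopifnot(inherits(truth, "synthetic_truth"))
  md <- transcriptome$metadata
  if (!all(truth$genes %in% md$gene_id)) {
    stop("transcriptome does not cover the truth's gene set")
  }
  tag_of_gene <- md$rank1_tag[match(truth$genes, md$gene_id)]
  set.seed(truth$seed + 7L)

  one_library <- function(n, p, lib) {
    fr <- c(adaptor = truth$adaptor_frac, lowq = truth$lowq_frac,
            mito = if (is.null(genomes)) 0 else truth$mito_frac,
            genome = if (is.null(genomes)) 0 else truth$genome_frac)
    cat_counts <- as.vector(stats::rmultinom(1, n, c(fr, signal = 1 - sum(fr))))
    names(cat_counts) <- c(names(fr), "signal")

    gene_counts <- as.vector(stats::rmultinom(1, cat_counts[["signal"]], p))
    signal <- rep(tag_of_gene, gene_counts)
    signal <- apply_sequencing_errors(signal, truth$error_rate)

    adaptor <- rep(DEFAULT_ADAPTOR, cat_counts[["adaptor"]])
    lowq <- rep(tag_of_gene[sample.int(length(p), cat_counts[["lowq"]],
                                       replace = TRUE, prob = p)],
                1L)
    if (length(lowq)) {
      pos <- sample.int(TAG_LEN, length(lowq), replace = TRUE)
      substring(lowq, pos, pos) <- "N"
    }
    mito <- if (is.null(genomes)) character(0) else
      sample_genome_reads(cat_counts[["mito"]], genomes$mito, exclude_tags)
    geno <- if (is.null(genomes)) character(0) else
      sample_genome_reads(cat_counts[["genome"]], genomes$nuclear,
                          c(exclude_tags, kmer_set(genomes$mito)))
    reads <- sample(c(signal, adaptor, lowq, mito, geno))
    list(reads = reads,
         ledger = data.frame(library = lib,
                             category = names(cat_counts),
                             n_reads = unname(cat_counts),
                             stringsAsFactors = FALSE))
  }
  lib1 <- one_library(truth$n1, truth$p1, "lib1")
  lib2 <- one_library(truth$n2, truth$p2, "lib2")
  list(reads1 = lib1$reads, reads2 = lib2$reads,
       ledger = rbind(lib1$ledger, lib2$ledger))
}

#' Fast count-level simulation of the two libraries
#'
#' Skips read-level simulation: draws the per-gene unambiguous counts
#' directly from the truth's multinomial model, for tests of the
#' differential-expression stage alone.
#'
#' @param truth a [synthetic_truth()].
#' @param seed optional seed override (defaults to the truth's).
#' @return list with `a` and `b` ([library_counts()]) and the truth.
#' @export
simulate_gene_counts <- function(truth, seed = truth$seed) {
  set.seed(seed + 13L)
  c1 <- as.vector(stats::rmultinom(1, truth$n1, truth$p1))
  c2 <- as.vector(stats::rmultinom(1, truth$n2, truth$p2))
  names(c1) <- names(c2) <- truth$genes
  list(a = library_counts("lib1", c1[c1 > 0], truth$n1),
       b = library_counts("lib2", c2[c2 > 0], truth$n2),
       truth = truth)
}

#' Generate a random term-membership table
#'
#' Random term memberships over the gene set; optionally one extra term
#' is loaded with a gene set of interest at a stated odds ratio so the
#' enrichment stage has a known positive (odds ratio 1 plants a null
#' term).
#'
#' @param genes character vector of gene ids.
#' @param n_terms number of random terms.
#' @param term_size_range min/max genes per term.
#' @param enriched optional list(genes=, size=, odds_ratio=): membership
#'   for the loaded term is sampled with weight `odds_ratio` for the
#'   listed genes and 1 otherwise.
#' @param seed integer seed.
#' @return list with `membership` (data.frame term_id, gene_id) and
#'   `info` (data.frame term_id, term_name, category); the loaded term,
#'   when requested, has term_id "T_PLANTED".
#' @export
generate_annotations <- function(genes, n_terms = 50,
                                 term_size_range = c(10, 100),
                                 enriched = NULL, seed = 1L) {
  set.seed(seed + 29L)
  cats <- c("biological_process", "cellular_component",
            "molecular_function", "pathway")
  sizes <- sample(seq(term_size_range[1], term_size_range[2]),
                  n_terms, replace = TRUE)
  ids <- sprintf("T%04d", seq_len(n_terms))
  membership <- do.call(rbind, lapply(seq_len(n_terms), function(i) {
    data.frame(term_id = ids[i],
               gene_id = sample(genes, min(sizes[i], length(genes))),
               stringsAsFactors = FALSE)
  }))
  info <- data.frame(term_id = ids,
                     term_name = paste0("synthetic term ", seq_len(n_terms)),
                     category = sample(cats, n_terms, replace = TRUE),
                     stringsAsFactors = FALSE)
  if (!is.null(enriched)) {
    size <- if (is.null(enriched$size)) mean(term_size_range) else
      enriched$size
    w <- ifelse(genes %in% enriched$genes, enriched$odds_ratio, 1)
    picked <- sample(genes, min(size, length(genes)), prob = w)
    membership <- rbind(membership,
                        data.frame(term_id = "T_PLANTED", gene_id = picked,
                                   stringsAsFactors = FALSE))
    info <- rbind(info,
                  data.frame(term_id = "T_PLANTED",
                             term_name = "planted term",
                             category = "biological_process",
                             stringsAsFactors = FALSE))
  }
  list(membership = membership, info = info, seed = seed)
}

#' Generate a synthetic long-format Ct table
#'
#' Plants true expression ratios (group_a over group_b) on target genes:
#' each animal's dCt is drawn around the gene's baseline with biological
#' noise, group_b animals are shifted by +log2(ratio); reference and
#' target Ct values are then emitted with technical-replicate noise.
#'
#' @param ratios named numeric vector: true group_a/group_b expression
#'   ratios per target gene.
#' @param groups two group labels (default c("A", "B")).
#' @param n_animals biological replicates per group (default 3).
#' @param n_tech technical replicates per gene and animal (default 3).
#' @param reference reference gene name (default "RPS20").
#' @param sd_bio,sd_tech biological / technical Ct standard deviations.
#' @param seed integer seed.
#' @return long-format data.frame (sample_id, group, gene_id, replicate,
#'   ct).
#' @export
generate_ct_table <- function(ratios, groups = c("A", "B"),
                              n_animals = 3, n_tech = 3,
                              reference = "RPS20", sd_bio = 0.25,
                              sd_tech = 0.1, seed = 1L) {
  set.seed(seed + 53L)
  targets <- names(ratios)
  rows <- list()
  for (gi in seq_along(groups)) {
    for (a in seq_len(n_animals)) {
      sample_id <- paste0(groups[gi], a)
      ct_ref <- stats::rnorm(1, 18, 0.3)
      for (r in seq_len(n_tech)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_id, group = groups[gi], gene_id = reference,
          replicate = r, ct = ct_ref + stats::rnorm(1, 0, sd_tech),
          stringsAsFactors = FALSE)
      }
      for (g in targets) {
        base_dct <- 4 + 2 * (match(g, targets) %% 3)
        dct <- base_dct + stats::rnorm(1, 0, sd_bio) +
          if (gi == 2L) log2(ratios[[g]]) else 0
        for (r in seq_len(n_tech)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sample_id, group = groups[gi], gene_id = g,
            replicate = r, ct = ct_ref + dct + stats::rnorm(1, 0, sd_tech),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector of sequences.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(sequences, file) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, file)
  invisible(file)
}
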