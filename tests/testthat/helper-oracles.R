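# Independent brute-force oracles and tiny fixture builders. These are
# deliberately written without reusing package internals, so the tests
# compare two separate routes to the same answer.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE),
                              collapse = "")

rand_tag <- function() paste0("CATG", rand_seq(17))

brute_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(map[strsplit(s, "")[[1]]])), collapse = "")
}

# exhaustive window scan of one strand: every position whose 4-mer is
# CATG and which has 17 nt downstream yields a tag; rank from the 3' end
brute_digest_strand <- function(s, strand, gene_id) {
  L <- nchar(s)
  rows <- list()
  for (i in seq_len(max(L - 3L, 0L))) {
    if (substr(s, i, i + 3L) == "CATG" && i + 20L <= L) {
      rows[[length(rows) + 1L]] <-
        data.frame(tag_seq = substr(s, i, i + 20L), gene_id = gene_id,
                   strand = strand, offset = i - 1L,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(tag_seq = character(0), gene_id = character(0),
                      strand = character(0), position_rank = integer(0),
                      offset = integer(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df$position_rank <- as.integer(rank(-df$offset))
  df <- df[!grepl("N", df$tag_seq, fixed = TRUE),
           c("tag_seq", "gene_id", "strand", "position_rank", "offset")]
  df
}

brute_digest <- function(s, gene_id = "gene") {
  out <- rbind(brute_digest_strand(s, "sense", gene_id),
               brute_digest_strand(brute_revcomp(s), "antisense", gene_id))
  rownames(out) <- NULL
  out
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# exhaustive-scan classification of a query against a reference tag
# table (tag_seq, gene_id, strand): best tier wins, sense beats
# antisense, one gene unambiguous, several ambiguous
brute_map <- function(query, ref) {
  d <- vapply(ref$tag_seq, hamming, numeric(1), a = query,
              USE.NAMES = FALSE)
  best <- min(d)
  if (best > 1) {
    return(list(category = "unknown", gene_id = NA_character_,
                mismatches = NA_integer_))
  }
  hits <- ref[d == best, , drop = FALSE]
  sg <- unique(hits$gene_id[hits$strand == "sense"])
  ag <- unique(hits$gene_id[hits$strand == "antisense"])
  if (length(sg) == 1L) {
    list(category = "gene_unambiguous", gene_id = sg, mismatches = best)
  } else if (length(sg) > 1L) {
    list(category = "gene_ambiguous", gene_id = NA_character_,
         mismatches = best)
  } else if (length(ag) == 1L) {
    list(category = "antisense_gene", gene_id = ag, mismatches = best)
  } else {
    list(category = "gene_ambiguous", gene_id = NA_character_,
         mismatches = best)
  }
}

# upper-tail hypergeometric p by direct pmf enumeration with choose()
brute_hyper_p <- function(k, K, n, N) {
  kk <- max(0, n + K - N):min(K, n)
  pmf <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  sum(pmf[kk >= k])
}

# Audic-Claverie two-sided p values from mpmath (dps = 60) tail
# summation, frozen before the package implementation was written
AC_ORACLE <- data.frame(
  x = c(5, 0, 3, 100, 25, 2, 40, 0, 12, 500, 7, 1000),
  n1 = c(1e6, 1e5, 1e5, 3448173, 200000, 1000, 500000, 1e4, 3448173,
         200000, 50000, 3448173),
  y = c(50, 10, 3, 150, 200, 7, 10, 0, 40, 450, 0, 1500),
  n2 = c(1e6, 1e5, 1e5, 5496993, 319000, 3000, 100000, 2e4, 5496993,
         319000, 80000, 5496993),
  p = c(2.1358426138817777e-10, 0.001953125, 1.0, 0.62462081237941293,
        6.0221985348613617e-20, 0.94881439208984375, 0.63391199062244457,
        0.66666666666666667, 0.027298032239987541, 1.4224460432683753e-18,
        0.00095773026550020053, 0.13509581822682403))

# small clean library fixture straight from named counts (bypasses the
# filter): counts must already be >= 2
clean_lib <- function(...) {
  clean_tag_library(c(...))
}
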