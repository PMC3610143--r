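# Annotation of clean tags against the reference tag library with at most
# one mismatch, cascading unmapped tags to the mitochondrial and nuclear
# genomes; gene counts, antisense report, tag-position profile.

TAG_CATEGORIES <- c("gene_unambiguous", "gene_ambiguous", "antisense_gene",
                    "mitochondrion", "genome", "unknown")

# per-tag-sequence summary of the reference library, used for
# classification: which sense/antisense genes carry each sequence
ref_seq_index <- function(library) {
  tags <- library$tags
  useq <- unique(tags$tag_seq)
  sid <- match(tags$tag_seq, useq)
  sense <- tags$strand == "sense"
  list(useq = useq,
       sense_genes = split(tags$gene_id[sense], factor(sid[sense],
                                                       seq_along(useq))),
       anti_genes = split(tags$gene_id[!sense], factor(sid[!sense],
                                                       seq_along(useq))),
       sense_rank = vapply(split(tags$position_rank[sense],
                                 factor(sid[sense], seq_along(useq))),
                           function(r) if (length(r)) min(r) else NA_integer_,
                           integer(1)))
}

# all Hamming-distance-1 neighbours of each query (21 positions x 3
# substitutions), as an (n_query x 63) character matrix
tag_neighbours <- function(tags) {
  n <- length(tags)
  # a column per (position, base) pair that differs from at least one
  # query; entries where the base equals the original are NA
  out <- matrix(NA_character_, nrow = n, ncol = 4L * TAG_LEN)
  bases <- c("A", "C", "G", "T")
  col <- 0L
  for (p in seq_len(TAG_LEN)) {
    orig <- substring(tags, p, p)
    pre <- substring(tags, 1L, p - 1L)
    post <- substring(tags, p + 1L, TAG_LEN)
    for (b in bases) {
      sub <- ifelse(orig == b, NA_character_, paste0(pre, b, post))
      if (all(is.na(sub)) && n > 0L) next
      col <- col + 1L
      out[, col] <- sub
    }
  }
  out[, seq_len(max(col, 1L)), drop = FALSE]
}

# classify one query given the reference rows it hits (possibly from
# several neighbouring sequences): sense wins over antisense at equal
# tier; a single gene is unambiguous, several are ambiguous
classify_hits <- function(sense_genes, anti_genes, sense_rank) {
  sg <- unique(sense_genes)
  if (length(sg) == 1L) {
    return(list(category = "gene_unambiguous", gene_id = sg,
                strand = "sense", position_rank = sense_rank))
  }
  if (length(sg) > 1L) {
    return(list(category = "gene_ambiguous", gene_id = NA_character_,
                strand = NA_character_, position_rank = NA_integer_))
  }
  ag <- unique(anti_genes)
  if (length(ag) == 1L) {
    return(list(category = "antisense_gene", gene_id = ag,
                strand = "antisense", position_rank = NA_integer_))
  }
  if (length(ag) > 1L) {
    return(list(category = "gene_ambiguous", gene_id = NA_character_,
                strand = NA_character_, position_rank = NA_integer_))
  }
  NULL
}

#' Map one tag against the reference tag library
#'
#' Exact matches take precedence over 1-mismatch matches. Within the best
#' tier, a single sense gene gives `gene_unambiguous`; a single antisense
#' gene with no sense hit gives `antisense_gene`; several distinct genes
#' give `gene_ambiguous`; sense hits win over antisense hits at equal
#' tier. A tag with no hit is a candidate for the genome cascade
#' (category `unknown` here).
#'
#' @param tag_seq a single 21-nt tag.
#' @param library a `ref_tag_library`.
#' @param max_mismatch 0 or 1 (default 1).
#' @return one-row data.frame: tag_seq, category, gene_id, strand,
#'   mismatches, position_rank.
#' @export
map_tag <- function(tag_seq, library, max_mismatch = 1L) {
  if (nchar(tag_seq) != TAG_LEN) {
    stop("tag must be ", TAG_LEN, " nt, got ", nchar(tag_seq))
  }
  idx <- ref_seq_index(library)
  ann <- map_tags_indexed(tag_seq, idx, max_mismatch)
  ann
}

# vectorised core: annotate unique tag sequences against a prebuilt index
map_tags_indexed <- function(tags, idx, max_mismatch = 1L) {
  n <- length(tags)
  out <- data.frame(tag_seq = tags,
                    category = rep("unknown", n),
                    gene_id = NA_character_,
                    strand = NA_character_,
                    mismatches = NA_integer_,
                    position_rank = NA_integer_,
                    stringsAsFactors = FALSE)
  # tier 0: exact
  hit0 <- match(tags, idx$useq)
  for (i in which(!is.na(hit0))) {
    s <- hit0[i]
    cl <- classify_hits(idx$sense_genes[[s]], idx$anti_genes[[s]],
                        idx$sense_rank[[s]])
    out$category[i] <- cl$category
    out$gene_id[i] <- cl$gene_id
    out$strand[i] <- cl$strand
    out$mismatches[i] <- 0L
    out$position_rank[i] <- cl$position_rank
  }
  # tier 1: Hamming distance 1, union over all neighbouring sequences
  rest <- which(is.na(hit0))
  if (max_mismatch >= 1L && length(rest)) {
    nb <- tag_neighbours(tags[rest])
    hits <- matrix(match(nb, idx$useq), nrow = length(rest))
    for (r in seq_along(rest)) {
      s <- unique(hits[r, ])
      s <- s[!is.na(s)]
      if (!length(s)) next
      cl <- classify_hits(unlist(idx$sense_genes[s], use.names = FALSE),
                          unlist(idx$anti_genes[s], use.names = FALSE),
                          suppressWarnings(min(idx$sense_rank[s],
                                               na.rm = TRUE)))
      if (is.null(cl)) next
      i <- rest[r]
      out$category[i] <- cl$category
      out$gene_id[i] <- cl$gene_id
      out$strand[i] <- cl$strand
      out$mismatches[i] <- 1L
      out$position_rank[i] <- if (is.finite(cl$position_rank))
        as.integer(cl$position_rank) else NA_integer_
    }
  }
  out
}

#' Map a clean tag library with the full annotation cascade
#'
#' Every unique clean tag is annotated in cascade order: reference tag
#' library (exact, then 1 mismatch) -> mitochondrial genome (exact 21-mer
#' on either strand) -> nuclear genome (exact) -> unknown. Each unique
#' tag receives exactly one category; totals weight by copy number. Gene
#' counts sum unambiguous sense annotations only; antisense annotations
#' are tallied separately by [antisense_report()].
#'
#' @param clean a [clean_tag_library()].
#' @param library a `ref_tag_library`.
#' @param mito optional mitochondrial genome sequence (single string).
#' @param genome optional nuclear genome sequence (single string).
#' @param max_mismatch mismatches allowed against the reference library
#'   (genome stages are always exact).
#' @return list with `annotations` (one row per unique tag, with its copy
#'   number), `summary` (a [mapping_summary()]) and `gene_counts`
#'   (data.frame gene_id/count).
#' @export
map_library <- function(clean, library, mito = NULL, genome = NULL,
                        max_mismatch = 1L) {
  if (library$n_total_tags == 0L) stop("empty reference library")
  tags <- clean$counts$tag_seq
  counts <- clean$counts$count
  idx <- ref_seq_index(library)
  ann <- map_tags_indexed(tags, idx, max_mismatch)
  ann$count <- counts

  todo <- ann$category == "unknown"
  if (!is.null(mito) && any(todo)) {
    mset <- kmer_set(toupper(mito))
    hit <- todo & ann$tag_seq %in% mset
    ann$category[hit] <- "mitochondrion"
    todo <- ann$category == "unknown"
  }
  if (!is.null(genome) && any(todo)) {
    gset <- kmer_set(toupper(genome))
    hit <- todo & ann$tag_seq %in% gset
    ann$category[hit] <- "genome"
  }

  gene_rows <- ann$category == "gene_unambiguous"
  gene_counts <- if (any(gene_rows)) {
    agg <- tapply(ann$count[gene_rows], ann$gene_id[gene_rows], sum)
    data.frame(gene_id = names(agg), count = as.integer(agg),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(0), count = integer(0),
               stringsAsFactors = FALSE)
  }
  gene_counts <- gene_counts[order(-gene_counts$count, gene_counts$gene_id), ,
                             drop = FALSE]
  rownames(gene_counts) <- NULL

  in_gene <- ann$category %in% c("gene_unambiguous", "gene_ambiguous",
                                 "antisense_gene")
  summ <- mapping_summary(
    total_clean = clean$total_clean,
    unique_clean = clean$n_unique,
    tags_mapped_to_gene = sum(ann$count[in_gene]),
    unique_tags_mapped_to_gene = sum(in_gene),
    unambiguous_tags_mapped_to_gene = sum(ann$count[gene_rows]),
    unique_unambiguous_tags_mapped_to_gene = sum(gene_rows),
    tags_mapped_to_mitochondrion = sum(ann$count[ann$category ==
                                                   "mitochondrion"]),
    unique_tags_mapped_to_mitochondrion = sum(ann$category ==
                                                "mitochondrion"),
    tags_mapped_to_genome = sum(ann$count[ann$category == "genome"]),
    unique_tags_mapped_to_genome = sum(ann$category == "genome"),
    unknown_tags = sum(ann$count[ann$category == "unknown"]),
    unique_unknown_tags = sum(ann$category == "unknown"))

  list(annotations = ann, summary = summ, gene_counts = gene_counts)
}

#' Mapping summary with percentage bookkeeping
#'
#' Holds the per-category census of a mapped clean library and derives
#' percentages of the clean totals: each total divided by `total_clean`
#' and each unique count divided by `unique_clean`, as percentages
#' rounded to 2 decimals.
#'
#' @param total_clean,unique_clean clean library totals.
#' @param tags_mapped_to_gene,unique_tags_mapped_to_gene all reference
#'   library hits (unambiguous + ambiguous + antisense).
#' @param unambiguous_tags_mapped_to_gene,unique_unambiguous_tags_mapped_to_gene
#'   sense single-gene hits only.
#' @param tags_mapped_to_mitochondrion,unique_tags_mapped_to_mitochondrion
#'   mitochondrial genome hits.
#' @param tags_mapped_to_genome,unique_tags_mapped_to_genome nuclear
#'   genome hits.
#' @param unknown_tags,unique_unknown_tags tags with no hit anywhere.
#' @return object of class `mapping_summary`: list of the counts plus a
#'   `pct` data.frame (category, total_pct, unique_pct).
#' @export
mapping_summary <- function(total_clean, unique_clean,
                            tags_mapped_to_gene,
                            unique_tags_mapped_to_gene,
                            unambiguous_tags_mapped_to_gene,
                            unique_unambiguous_tags_mapped_to_gene,
                            tags_mapped_to_mitochondrion = 0,
                            unique_tags_mapped_to_mitochondrion = 0,
                            tags_mapped_to_genome = 0,
                            unique_tags_mapped_to_genome = 0,
                            unknown_tags = 0,
                            unique_unknown_tags = 0) {
  totals <- c("Tags Mapped to Gene" = tags_mapped_to_gene,
              "Unambiguous Tags Mapped to Gene" =
                unambiguous_tags_mapped_to_gene,
              "Tags Mapped to Mitochondrion" = tags_mapped_to_mitochondrion,
              "Tags Mapped to Genome" = tags_mapped_to_genome,
              "Unknown Tags" = unknown_tags)
  uniques <- c(unique_tags_mapped_to_gene,
               unique_unambiguous_tags_mapped_to_gene,
               unique_tags_mapped_to_mitochondrion,
               unique_tags_mapped_to_genome,
               unique_unknown_tags)
  pct <- data.frame(category = names(totals),
                    total_tags = unname(totals),
                    unique_tags = uniques,
                    total_pct = round(100 * unname(totals) / total_clean, 2),
                    unique_pct = round(100 * uniques / unique_clean, 2),
                    stringsAsFactors = FALSE)
  structure(list(total_clean = total_clean, unique_clean = unique_clean,
                 counts = totals, unique_counts = uniques, pct = pct),
            class = "mapping_summary")
}

#' @export
print.mapping_summary <- function(x, ...) {
  cat("Mapping summary (clean total", x$total_clean, "/ unique",
      x$unique_clean, ")\n")
  print(x$pct, row.names = FALSE)
  invisible(x)
}

#' Copy-number-weighted tag position profile
#'
#' Histogram of the 3'-position ranks of gene-mapped tags, weighted by
#' copy number; also reports the fraction of copies at rank 1 (the
#' 3'-most NlaIII site).
#'
#' @param annotations annotation data.frame from [map_library()] (rows
#'   without a position rank are ignored).
#' @return list with `histogram` (data.frame position_rank, total_tags,
#'   unique_tags) and `fraction_rank1`.
#' @export
tag_position_profile <- function(annotations) {
  keep <- !is.na(annotations$position_rank)
  if (!any(keep)) {
    return(list(histogram = data.frame(position_rank = integer(0),
                                       total_tags = integer(0),
                                       unique_tags = integer(0)),
                fraction_rank1 = NA_real_))
  }
  a <- annotations[keep, , drop = FALSE]
  w <- if ("count" %in% names(a)) a$count else rep(1L, nrow(a))
  tot <- tapply(w, a$position_rank, sum)
  uni <- tapply(w, a$position_rank, length)
  hist <- data.frame(position_rank = as.integer(names(tot)),
                     total_tags = as.integer(tot),
                     unique_tags = as.integer(uni))
  hist <- hist[order(hist$position_rank), , drop = FALSE]
  rownames(hist) <- NULL
  list(histogram = hist,
       fraction_rank1 = sum(w[a$position_rank == 1L]) / sum(w))
}

#' Antisense transcription report
#'
#' One row per gene with at least one antisense-mapped tag: the number of
#' distinct antisense tags and their summed copies, sorted by copy total
#' descending.
#'
#' @param annotations annotation data.frame from [map_library()].
#' @return data.frame (gene_id, unique_tags, total_tags).
#' @export
antisense_report <- function(annotations) {
  sel <- annotations$category == "antisense_gene"
  if (!any(sel)) {
    return(data.frame(gene_id = character(0), unique_tags = integer(0),
                      total_tags = integer(0), stringsAsFactors = FALSE))
  }
  a <- annotations[sel, , drop = FALSE]
  w <- if ("count" %in% names(a)) a$count else rep(1L, nrow(a))
  tot <- tapply(w, a$gene_id, sum)
  uni <- tapply(w, a$gene_id, length)
  out <- data.frame(gene_id = names(tot),
                    unique_tags = as.integer(uni),
                    total_tags = as.integer(tot),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$total_tags, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
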