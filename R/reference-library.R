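# Virtual reference tag library: in-silico NlaIII/MmeI digestion of a
# prioritised transcript database, on both strands.

#' Build a transcript record table
#'
#' @param gene_id character vector of gene identifiers.
#' @param sequence character vector of nucleotide sequences (A/C/G/T/N).
#' @param source database name each record came from.
#' @param priority integer rank of the source, 1 = highest priority.
#' @return data.frame with columns gene_id, source, priority, sequence.
#' @export
transcript_records <- function(gene_id, sequence, source = "user",
                               priority = 1L) {
  sequence <- toupper(sequence)
  check_nucleotides(sequence)
  if (any(!nzchar(sequence))) stop("empty transcript sequence")
  if (any(priority < 1L)) stop("priority must be >= 1")
  data.frame(gene_id = as.character(gene_id),
             source = rep_len(as.character(source), length(gene_id)),
             priority = rep_len(as.integer(priority), length(gene_id)),
             sequence = sequence,
             stringsAsFactors = FALSE)
}

#' Read transcript databases from FASTA files
#'
#' Each file carries a source name and a priority rank; records are
#' concatenated and can then be reduced with [merge_databases()].
#'
#' @param files paths to FASTA files.
#' @param sources character vector of database names, one per file.
#' @param priorities integer vector of priority ranks, one per file
#'   (1 = highest).
#' @return data.frame of transcript records.
#' @export
read_transcript_fasta <- function(files, sources = files,
                                  priorities = seq_along(files)) {
  stopifnot(length(files) == length(sources),
            length(files) == length(priorities))
  recs <- lapply(seq_along(files), function(i) {
    ss <- Biostrings::readDNAStringSet(files[i])
    transcript_records(gene_id = sub("\\s.*$", "", names(ss)),
                       sequence = as.character(ss),
                       source = sources[i],
                       priority = priorities[i])
  })
  do.call(rbind, recs)
}

#' Merge transcript databases by source priority
#'
#' When the same gene (after optional cross-reference translation) appears
#' in several sources, only the record from the highest-priority source is
#' kept. Ties within a priority level keep the first occurrence and emit a
#' warning.
#'
#' @param records data.frame as from [transcript_records()].
#' @param xref optional data.frame (source_id, canonical_id) translating
#'   per-database identifiers to a shared gene identifier before
#'   comparison; identifiers absent from the table are used verbatim.
#' @return merged data.frame of transcript records, gene_id rewritten to
#'   the canonical identifier where a cross-reference applied.
#' @export
merge_databases <- function(records, xref = NULL) {
  if (is.null(records) || nrow(records) == 0L) return(records)
  if (!is.null(xref)) {
    i <- match(records$gene_id, xref[[1]])
    records$gene_id <- ifelse(is.na(i), records$gene_id,
                              as.character(xref[[2]])[i])
  }
  ord <- order(records$priority, seq_len(nrow(records)))
  records <- records[ord, , drop = FALSE]
  dup <- duplicated(records$gene_id)
  if (any(dup)) {
    # flag equal-priority conflicts explicitly
    kept_pri <- records$priority[match(records$gene_id, records$gene_id)]
    tie <- dup & records$priority == kept_pri
    if (any(tie)) {
      warning("duplicate gene_id at equal priority; first occurrence kept: ",
              paste(unique(records$gene_id[tie]), collapse = ", "))
    }
  }
  out <- records[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Digest one transcript into reference tags
#'
#' Scans both strands (sense = the given sequence, antisense = its reverse
#' complement) for the NlaIII recognition site CATG and emits one 21-nt tag
#' (CATG + the next 17 nt, the MmeI release) per site with at least 17 nt
#' downstream. Sites are ranked per strand from the 3' end: rank 1 is the
#' 3'-most site that yields a full-length tag. Tags containing N are
#' dropped.
#'
#' @param sequence a single nucleotide string over {A,C,G,T,N}.
#' @param gene_id identifier recorded on each tag.
#' @return data.frame with columns tag_seq, gene_id, strand
#'   ("sense"/"antisense"), position_rank, offset (0-based position of the
#'   CATG start in the strand-oriented sequence).
#' @export
digest_transcript <- function(sequence, gene_id = "gene") {
  stopifnot(length(sequence) == 1L)
  sequence <- toupper(sequence)
  check_nucleotides(sequence)
  one_strand <- function(s, strand) {
    hits <- gregexpr(ANCHOR, s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) hits <- integer(0)
    full <- hits[hits + TAG_LEN - 1L <= nchar(s)]
    if (!length(full)) {
      return(data.frame(tag_seq = character(0), gene_id = character(0),
                        strand = character(0), position_rank = integer(0),
                        offset = integer(0), stringsAsFactors = FALSE))
    }
    full <- sort(full)
    rank <- rev(seq_along(full))   # 3'-most full-length site gets rank 1
    tags <- substring(s, full, full + TAG_LEN - 1L)
    df <- data.frame(tag_seq = tags, gene_id = gene_id, strand = strand,
                     position_rank = rank, offset = full - 1L,
                     stringsAsFactors = FALSE)
    df[!grepl("N", df$tag_seq, fixed = TRUE), , drop = FALSE]
  }
  out <- rbind(one_strand(sequence, "sense"),
               one_strand(revcomp(sequence), "antisense"))
  rownames(out) <- NULL
  out
}

#' Build the reference tag library
#'
#' Digests every (already merged) transcript record and groups the
#' resulting tags by sequence. A tag sequence associated with exactly one
#' gene — regardless of how many positions or strands it occupies within
#' that gene — is unambiguous.
#'
#' @param records merged data.frame of transcript records.
#' @return object of class `ref_tag_library`: a list with `tags` (one row
#'   per gene/strand/position occurrence, with an `ambiguous` flag),
#'   `n_total_tags` (distinct tag sequences) and `n_unambiguous_tags`.
#' @export
build_reference_library <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    tags <- data.frame(tag_seq = character(0), gene_id = character(0),
                       strand = character(0), position_rank = integer(0),
                       offset = integer(0), source = character(0),
                       ambiguous = logical(0), stringsAsFactors = FALSE)
    return(structure(list(tags = tags, n_total_tags = 0L,
                          n_unambiguous_tags = 0L),
                     class = "ref_tag_library"))
  }
  pieces <- lapply(seq_len(nrow(records)), function(i) {
    df <- digest_transcript(records$sequence[i], records$gene_id[i])
    if (nrow(df)) df$source <- records$source[i] else df$source <- character(0)
    df
  })
  tags <- do.call(rbind, pieces)
  rownames(tags) <- NULL
  if (nrow(tags) == 0L) {
    tags$ambiguous <- logical(0)
    return(structure(list(tags = tags, n_total_tags = 0L,
                          n_unambiguous_tags = 0L),
                     class = "ref_tag_library"))
  }
  genes_per_tag <- tapply(tags$gene_id, tags$tag_seq,
                          function(g) length(unique(g)))
  tags$ambiguous <- genes_per_tag[tags$tag_seq] > 1L
  structure(list(tags = tags,
                 n_total_tags = length(genes_per_tag),
                 n_unambiguous_tags = sum(genes_per_tag == 1L)),
            class = "ref_tag_library")
}

#' @export
print.ref_tag_library <- function(x, ...) {
  cat("Reference tag library\n")
  cat("  distinct tag sequences:", x$n_total_tags, "\n")
  cat("  unambiguous (single-gene) tags:", x$n_unambiguous_tags, "\n")
  cat("  occurrence rows:", nrow(x$tags), "\n")
  invisible(x)
}

#' Write / read a reference tag library as TSV
#'
#' @param library a `ref_tag_library`.
#' @param file path to the TSV file.
#' @param meta optional named list written into the provenance line.
#' @return `write_reference_library` the path, invisibly;
#'   `read_reference_library` a `ref_tag_library`.
#' @export
write_reference_library <- function(library, file, meta = NULL) {
  write_report(library$tags, file, meta = meta)
}

#' @rdname write_reference_library
#' @export
read_reference_library <- function(file) {
  tags <- read_report(file)
  tags$ambiguous <- as.logical(tags$ambiguous)
  genes_per_tag <- tapply(tags$gene_id, tags$tag_seq,
                          function(g) length(unique(g)))
  structure(list(tags = tags,
                 n_total_tags = length(genes_per_tag),
                 n_unambiguous_tags = sum(genes_per_tag == 1L)),
            class = "ref_tag_library")
}
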