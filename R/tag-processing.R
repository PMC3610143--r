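# Raw-tag filtering, the conservation ledger, copy-number bins and
# saturation (rarefaction) curves.

#' Construct a filtering ledger
#'
#' Bookkeeping for the raw-to-clean filter cascade. The clean total is
#' derived by conservation: n_clean = n_raw - n_low_quality - n_adaptor -
#' n_singleton.
#'
#' @param n_raw total raw reads.
#' @param n_low_quality reads removed as low quality (containing N or a
#'   base below the quality threshold).
#' @param n_adaptor reads removed as adaptor matches.
#' @param n_singleton reads removed because their tag had library copy
#'   number 1 after the other filters.
#' @return object of class `filter_ledger` (a named list including the
#'   derived `n_clean`).
#' @export
filter_ledger <- function(n_raw, n_low_quality = 0, n_adaptor = 0,
                          n_singleton = 0) {
  counts <- c(n_raw = n_raw, n_low_quality = n_low_quality,
              n_adaptor = n_adaptor, n_singleton = n_singleton)
  if (any(counts < 0)) stop("ledger counts must be non-negative")
  n_clean <- n_raw - n_low_quality - n_adaptor - n_singleton
  if (n_clean < 0) stop("filter categories exceed the raw total")
  structure(list(n_raw = n_raw, n_low_quality = n_low_quality,
                 n_adaptor = n_adaptor, n_singleton = n_singleton,
                 n_clean = n_clean),
            class = "filter_ledger")
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat(sprintf("Raw Data        %12.0f\n", x$n_raw))
  cat(sprintf("Low Quality Tag %12.0f\n", x$n_low_quality))
  cat(sprintf("Adaptors        %12.0f\n", x$n_adaptor))
  cat(sprintf("Tag CopyNum <2  %12.0f\n", x$n_singleton))
  cat(sprintf("Clean Tags      %12.0f\n", x$n_clean))
  invisible(x)
}

#' Construct a clean tag library
#'
#' @param counts data.frame (tag_seq, count) or a named integer vector of
#'   copy numbers; every copy number must be >= 2.
#' @return object of class `clean_tag_library`: list with `counts` (a
#'   data.frame tag_seq/count), `total_clean` and `n_unique`.
#' @export
clean_tag_library <- function(counts) {
  if (is.numeric(counts) && !is.null(names(counts))) {
    counts <- data.frame(tag_seq = names(counts),
                         count = as.integer(unname(counts)),
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(c("tag_seq", "count") %in% names(counts)))
  if (any(counts$count < 2L)) {
    stop("clean tag library may not contain copy numbers < 2")
  }
  if (anyDuplicated(counts$tag_seq)) stop("duplicated tag sequences")
  structure(list(counts = counts,
                 total_clean = sum(counts$count),
                 n_unique = nrow(counts)),
            class = "clean_tag_library")
}

#' @export
print.clean_tag_library <- function(x, ...) {
  cat("Clean tag library:", x$total_clean, "tags,",
      x$n_unique, "unique\n")
  invisible(x)
}

#' Filter raw sequencer tags to a clean tag library
#'
#' Reads are removed in a fixed order: adaptor matches first, then
#' low-quality reads (containing N, or any base below `min_quality` when
#' per-base qualities are supplied), then singleton reads — reads whose
#' tag has copy number 1 in the post-quality multiset. Each removal is
#' recorded in the ledger, which conserves the raw total.
#'
#' @param tags character vector of raw 21-nt tag reads.
#' @param qualities optional character vector of Phred+33 quality strings,
#'   one per read; when absent only the N rule defines low quality.
#' @param adaptor_seqs character vector of adaptor sequences; a read
#'   containing any of them as a substring is removed.
#' @param min_quality Phred threshold below which a base marks its read as
#'   low quality. Default 10.
#' @return list with `clean` (a [clean_tag_library()]) and `ledger` (a
#'   [filter_ledger()]).
#' @export
filter_raw_tags <- function(tags, qualities = NULL,
                            adaptor_seqs = character(0),
                            min_quality = 10) {
  n_raw <- length(tags)
  if (n_raw == 0L) {
    empty <- data.frame(tag_seq = character(0), count = integer(0),
                        stringsAsFactors = FALSE)
    return(list(clean = structure(list(counts = empty, total_clean = 0L,
                                       n_unique = 0L),
                                  class = "clean_tag_library"),
                ledger = filter_ledger(0, 0, 0, 0)))
  }
  is_adaptor <- rep(FALSE, n_raw)
  for (ad in adaptor_seqs) {
    is_adaptor <- is_adaptor | grepl(ad, tags, fixed = TRUE)
  }
  n_adaptor <- sum(is_adaptor)
  tags2 <- tags[!is_adaptor]
  qual2 <- if (!is.null(qualities)) qualities[!is_adaptor] else NULL

  lowq <- grepl("N", tags2, fixed = TRUE)
  if (!is.null(qual2)) {
    minq <- vapply(qual2, function(q) {
      if (is.na(q) || !nzchar(q)) return(Inf)
      min(utf8ToInt(q)) - 33
    }, numeric(1), USE.NAMES = FALSE)
    lowq <- lowq | minq < min_quality
  }
  n_low_quality <- sum(lowq)
  tags3 <- tags2[!lowq]

  tab <- table(tags3)
  singleton_tags <- names(tab)[tab == 1L]
  n_singleton <- length(singleton_tags)
  keep <- tab[tab >= 2L]

  counts <- data.frame(tag_seq = names(keep), count = as.integer(keep),
                       stringsAsFactors = FALSE)
  counts <- counts[order(-counts$count, counts$tag_seq), , drop = FALSE]
  rownames(counts) <- NULL
  list(clean = clean_tag_library(counts),
       ledger = filter_ledger(n_raw, n_low_quality, n_adaptor, n_singleton))
}

#' Copy-number distribution of a clean tag library
#'
#' Tabulates, for each threshold t, the summed copies and the number of
#' distinct tags with copy number > t; the first threshold is inclusive
#' (>=), matching the convention that the clean library itself is the
#' "copy number >= 2" row.
#'
#' @param clean a [clean_tag_library()].
#' @param thresholds ascending integer thresholds; default
#'   `c(2, 5, 10, 20, 50, 100)`.
#' @return data.frame (label, threshold, total_tags, unique_tags).
#' @export
copy_number_distribution <- function(clean,
                                     thresholds = c(2, 5, 10, 20, 50, 100)) {
  stopifnot(!is.unsorted(thresholds, strictly = TRUE))
  cn <- clean$counts$count
  rows <- lapply(seq_along(thresholds), function(i) {
    t <- thresholds[i]
    sel <- if (i == 1L) cn >= t else cn > t
    data.frame(label = if (i == 1L) paste0("CopyNum >=", t)
               else paste0("CopyNum >", t),
               threshold = t,
               total_tags = sum(cn[sel]),
               unique_tags = sum(sel),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Saturation (rarefaction) analysis of a tag stream
#'
#' Shuffles the read stream once with the given seed (sampling without
#' replacement, i.e. a cumulative-sequencing interpretation), then scans
#' prefixes of size `step`, `2*step`, ... and records the number of
#' distinct unique tags — and, when a tag-to-gene resolver is supplied,
#' distinct genes — seen so far, together with each point's percentage of
#' the final value. The last point always covers the full stream.
#'
#' @param reads character vector: the tag stream, one element per read.
#' @param step prefix increment (>= 1).
#' @param resolver optional: a named character vector mapping tag_seq to
#'   gene_id, or a function taking tag sequences and returning gene ids
#'   (NA = unmapped).
#' @param seed integer seed for the single shuffle.
#' @return data.frame of class `saturation_curve` with columns
#'   n_tags_sampled, n_distinct_unique_tags, pct_unique_tags and (with a
#'   resolver) n_distinct_genes, pct_genes.
#' @export
saturation_analysis <- function(reads, step, resolver = NULL, seed = 1L) {
  stopifnot(step >= 1L)
  n <- length(reads)
  if (n == 0L) {
    out <- data.frame(n_tags_sampled = integer(0),
                      n_distinct_unique_tags = integer(0),
                      pct_unique_tags = numeric(0))
    class(out) <- c("saturation_curve", class(out))
    return(out)
  }
  set.seed(seed)
  shuffled <- sample(reads, n, replace = FALSE)
  sizes <- if (step >= n) n else unique(c(seq(step, n, by = step), n))
  cum_tags <- cumsum(!duplicated(shuffled))
  out <- data.frame(n_tags_sampled = sizes,
                    n_distinct_unique_tags = cum_tags[sizes])
  out$pct_unique_tags <- 100 * out$n_distinct_unique_tags / cum_tags[n]
  if (!is.null(resolver)) {
    genes <- if (is.function(resolver)) resolver(shuffled)
             else unname(resolver[shuffled])
    new_gene <- !is.na(genes) & !duplicated(genes, incomparables = NA)
    cum_genes <- cumsum(new_gene)
    out$n_distinct_genes <- cum_genes[sizes]
    final <- max(cum_genes[n], 1L)
    out$pct_genes <- 100 * out$n_distinct_genes / final
  }
  class(out) <- c("saturation_curve", class(out))
  out
}
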