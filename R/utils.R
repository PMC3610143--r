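# shared low-level helpers

TAG_LEN <- 21L
ANCHOR <- "CATG"
ANCHOR_LEN <- 4L
DOWNSTREAM_LEN <- 17L

#' Reverse complement of a nucleotide string
#'
#' Plain-character reverse complement over the alphabet {A,C,G,T,N}.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

check_nucleotides <- function(x, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop("non-nucleotide characters in sequence(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  invisible(TRUE)
}

# log(sum(exp(lx))) without overflow; lx may be length 0 (-Inf)
logsumexp <- function(lx) {
  if (length(lx) == 0L) return(-Inf)
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

# all k-mers of a sequence on both strands, as a character vector
kmer_set <- function(seq, k = TAG_LEN) {
  seqs <- c(seq, revcomp(seq))
  out <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    starts <- seq_len(n - k + 1L)
    substring(s, starts, starts + k - 1L)
  }))
  unique(out[!grepl("N", out, fixed = TRUE)])
}

#' Write / read a provenance-stamped TSV report
#'
#' The on-disk format every pipeline table uses: an optional "##"
#' provenance line (key=value pairs, typically the config hash and
#' seed), a "#"-prefixed tab-separated header line, then the rows.
#' Bit-exact diffable.
#'
#' @param df data.frame to write.
#' @param file path.
#' @param meta optional named list for the provenance line.
#' @return `write_report` the path invisibly; `read_report` a
#'   data.frame.
#' @export
write_report <- function(df, file, meta = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(paste0("## ", paste(names(meta), unlist(meta),
                                   sep = "=", collapse = " ")), con)
  }
  writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
  if (nrow(df)) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(file)
}

#' @rdname write_report
#' @export
read_report <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^# ", lines)[1]
  cols <- strsplit(sub("^# ", "", lines[hdr]), "\t", fixed = TRUE)[[1]]
  body <- lines[-seq_len(hdr)]
  if (!length(body)) {
    df <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(df) <- cols
    return(df)
  }
  df <- utils::read.table(text = body, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  names(df) <- cols
  df
}
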