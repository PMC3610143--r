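# TPM normalisation, the Audic-Claverie exact test for two tag
# libraries, BH false discovery rate, and the three-threshold DE call.

#' Tags-per-million normalisation
#'
#' TPM = count / total_clean * 1e6. Zero counts are reported at a small
#' floor so that fold changes remain defined for presence/absence genes.
#'
#' @param count non-negative integer count(s).
#' @param total_clean library size: total clean tags (> 0).
#' @param zero_floor TPM value substituted for zero counts (default 0.01).
#' @return numeric TPM value(s).
#' @export
normalize_tpm <- function(count, total_clean, zero_floor = 0.01) {
  if (any(total_clean <= 0)) stop("total_clean must be positive")
  if (any(count < 0)) stop("counts must be non-negative")
  tpm <- count / total_clean * 1e6
  tpm[count == 0] <- zero_floor
  tpm
}

# log pmf of the Audic-Claverie conditional:
#   P(j | x) = (N2/N1)^j (x+j)! / ( x! j! (1 + N2/N1)^(x+j+1) )
# i.e. a negative binomial in j with size x+1 and prob N1/(N1+N2)
ac_log_pmf <- function(j, x, log_r, log_1r) {
  j * log_r + lgamma(x + j + 1) - lgamma(x + 1) - lgamma(j + 1) -
    (x + j + 1) * log_1r
}

# two-sided Audic-Claverie p for a single (x, y) pair, summed in log space
ac_test_one <- function(x, n1, y, n2) {
  log_r <- log(n2) - log(n1)
  log_1r <- log1p(n2 / n1)
  lower <- logsumexp(ac_log_pmf(0:y, x, log_r, log_1r))
  # upper tail: sum from y upward until terms are negligible relative to
  # the running maximum (the pmf decays geometrically past its mode)
  mode_j <- (x + 1) * n2 / n1
  sd_j <- sqrt((x + 1) * (n2 / n1) * (1 + n2 / n1))
  hi <- ceiling(max(y, mode_j + 20 * sd_j + 50))
  repeat {
    lt <- ac_log_pmf(y:hi, x, log_r, log_1r)
    if (lt[length(lt)] < max(lt) - 70 || hi > y + 1e8) break
    hi <- 2L * hi + 100L
  }
  upper <- logsumexp(lt)
  min(1, 2 * exp(min(lower, upper)))
}

#' Audic-Claverie exact test for two count libraries
#'
#' Tests whether a transcript's abundance differs between two tag
#' libraries of sizes N1 and N2, conditioning on the count x observed in
#' the first. Under the null the second library's count y follows
#' P(y | x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1)). The one-tail
#' p-value is the smaller of the lower (sum over j <= y) and upper (sum
#' over j >= y) tails; the two-sided p doubles it, capped at 1. All sums
#' are accumulated in log space.
#'
#' @param x count(s) in library 1.
#' @param n1 total clean tags in library 1.
#' @param y count(s) in library 2 (recycled against x).
#' @param n2 total clean tags in library 2.
#' @return vector of two-sided p-values in [0, 1].
#' @export
ac_test <- function(x, n1, y, n2) {
  if (any(c(x, y) < 0) || any(c(n1, n2) <= 0)) {
    stop("counts must be non-negative and library sizes positive")
  }
  mapply(ac_test_one, x = x, y = y,
         MoreArgs = list(n1 = n1, n2 = n2), USE.NAMES = FALSE)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted p-values with monotonicity enforcement, in the input
#' order (delegates to [stats::p.adjust()]).
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return vector of BH-adjusted values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Bundle per-library gene counts with the library size
#'
#' @param label library name.
#' @param gene_counts data.frame (gene_id, count) or named integer vector.
#' @param total_clean total clean tags of the library (the TPM
#'   denominator); must be at least the sum of the gene counts.
#' @return object of class `library_counts`.
#' @export
library_counts <- function(label, gene_counts, total_clean) {
  if (is.numeric(gene_counts) && !is.null(names(gene_counts))) {
    gene_counts <- data.frame(gene_id = names(gene_counts),
                              count = as.integer(unname(gene_counts)),
                              stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene_id", "count") %in% names(gene_counts)))
  if (sum(gene_counts$count) > total_clean) {
    stop("gene counts exceed the clean total")
  }
  structure(list(label = label, gene_counts = gene_counts,
                 total_clean = total_clean),
            class = "library_counts")
}

#' Two-library differential expression call
#'
#' Unions the gene universes of the two libraries (a gene absent from one
#' gets count 0 there), computes floored TPMs and log2 fold changes, the
#' Audic-Claverie two-sided p per gene, BH FDR across genes, and flags a
#' gene significant when p < `p_max`, FDR < `fdr_max` and
#' |log2FC| > `lfc_min` all hold.
#'
#' @param a,b [library_counts()] objects.
#' @param p_max,fdr_max,lfc_min significance thresholds (defaults 0.001,
#'   0.001, 2).
#' @param zero_floor TPM floor for zero counts, see [normalize_tpm()].
#' @return data.frame of class `de_result`, sorted by FDR then p:
#'   gene_id, count_a, count_b, tpm_a, tpm_b, log2fc, p_value, fdr,
#'   significant.
#' @export
call_de <- function(a, b, p_max = 0.001, fdr_max = 0.001, lfc_min = 2,
                    zero_floor = 0.01) {
  stopifnot(inherits(a, "library_counts"), inherits(b, "library_counts"))
  genes <- union(a$gene_counts$gene_id, b$gene_counts$gene_id)
  xa <- a$gene_counts$count[match(genes, a$gene_counts$gene_id)]
  xb <- b$gene_counts$count[match(genes, b$gene_counts$gene_id)]
  xa[is.na(xa)] <- 0L
  xb[is.na(xb)] <- 0L
  tpm_a <- normalize_tpm(xa, a$total_clean, zero_floor)
  tpm_b <- normalize_tpm(xb, b$total_clean, zero_floor)
  p <- ac_test(xa, a$total_clean, xb, b$total_clean)
  fdr <- bh_fdr(p)
  log2fc <- log2(tpm_a / tpm_b)
  out <- data.frame(gene_id = genes, count_a = xa, count_b = xb,
                    tpm_a = tpm_a, tpm_b = tpm_b, log2fc = log2fc,
                    p_value = p, fdr = fdr,
                    significant = p < p_max & fdr < fdr_max &
                      abs(log2fc) > lfc_min,
                    stringsAsFactors = FALSE)
  out <- out[order(out$fdr, out$p_value, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("de_result", class(out))
  out
}

#' Percentage of a total at three significant digits
#'
#' Reporting convention for gene-set proportions: 100 * count / total,
#' rounded to three significant digits.
#'
#' @param count numerator count(s).
#' @param total denominator.
#' @return numeric percentage(s).
#' @export
pct_of_total <- function(count, total) {
  signif(100 * count / total, 3)
}

#' Partition two gene sets into unique and shared fractions
#'
#' @param genes_a,genes_b character vectors of detected gene ids.
#' @return data.frame with rows unique_a, unique_b, shared: the count and
#'   its percentage of the combined universe (three significant digits).
#' @export
gene_partition <- function(genes_a, genes_b) {
  genes_a <- unique(genes_a)
  genes_b <- unique(genes_b)
  universe <- length(union(genes_a, genes_b))
  counts <- c(unique_a = length(setdiff(genes_a, genes_b)),
              unique_b = length(setdiff(genes_b, genes_a)),
              shared = length(intersect(genes_a, genes_b)))
  data.frame(set = names(counts), count = unname(counts),
             universe = universe,
             pct = pct_of_total(unname(counts), universe),
             stringsAsFactors = FALSE)
}
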