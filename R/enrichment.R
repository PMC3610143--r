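# Hypergeometric GO-term / pathway enrichment with Bonferroni-adjusted
# significance.

#' Hypergeometric enrichment of a gene list against a background
#'
#' For each term with at least one background member, tests whether the
#' differential genes over-represent the term: with N background genes, K
#' of them in the term, n differential genes and k of those in the term,
#' p = P(X >= k) for X ~ hypergeometric(N, K, n). Q-values are Bonferroni
#' adjusted (p times the number of tested terms); when term categories
#' are supplied, the correction is applied within each category.
#'
#' @param de_genes character vector of differential gene ids; must be a
#'   subset of `background`.
#' @param background character vector: the gene universe (genes without
#'   any term annotation still count toward N).
#' @param terms data.frame (term_id, gene_id) of term memberships.
#' @param term_info optional data.frame (term_id, term_name, category).
#' @param q_max significance threshold on the Q-value (default 0.05).
#' @return data.frame sorted by q then p: term_id, term_name, category,
#'   k, K, n, N, p_value, q_value, significant.
#' @export
hypergeom_enrich <- function(de_genes, background, terms,
                             term_info = NULL, q_max = 0.05) {
  de_genes <- unique(de_genes)
  background <- unique(background)
  stray <- setdiff(de_genes, background)
  if (length(stray)) {
    stop("differential genes missing from the background: ",
         paste(utils::head(stray, 10), collapse = ", "))
  }
  stopifnot(all(c("term_id", "gene_id") %in% names(terms)))
  terms <- terms[terms$gene_id %in% background, , drop = FALSE]
  members <- split(unique(terms[c("term_id", "gene_id")])$gene_id,
                   unique(terms[c("term_id", "gene_id")])$term_id)
  members <- members[lengths(members) > 0L]
  if (!length(members)) {
    out <- data.frame(term_id = character(0), term_name = character(0),
                      category = character(0), k = integer(0),
                      K = integer(0), n = integer(0), N = integer(0),
                      p_value = numeric(0), q_value = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
    return(out)
  }
  N <- length(background)
  n <- length(de_genes)
  K <- lengths(members)
  k <- vapply(members, function(g) sum(g %in% de_genes), integer(1))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)

  ids <- names(members)
  nm <- rep(NA_character_, length(ids))
  cat_ <- rep("all", length(ids))
  if (!is.null(term_info)) {
    i <- match(ids, term_info$term_id)
    if ("term_name" %in% names(term_info)) nm <- term_info$term_name[i]
    if ("category" %in% names(term_info)) {
      cat_ <- ifelse(is.na(i), "all", as.character(term_info$category[i]))
    }
  }
  n_tested <- stats::ave(p, cat_, FUN = length)
  q <- pmin(1, p * n_tested)

  out <- data.frame(term_id = ids, term_name = nm, category = cat_,
                    k = k, K = as.integer(K), n = n, N = N,
                    p_value = p, q_value = q, significant = q < q_max,
                    stringsAsFactors = FALSE)
  out <- out[order(out$q_value, out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
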