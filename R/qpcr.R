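# 2^-ddCt relative quantification with reference-gene normalisation and
# a Welch two-group test on per-animal dCt values.

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged per sample and gene; each sample's
#' dCt is Ct(target) - Ct(reference); ddCt is the group_a mean dCt minus
#' the group_b mean dCt; the expression ratio of group_a relative to
#' group_b is 2^(-ddCt). Groups are compared with a two-sided Welch
#' t-test on the per-sample dCt values.
#'
#' @param ct_table long-format data.frame with columns sample_id, group,
#'   gene_id, replicate, ct.
#' @param target gene to quantify.
#' @param reference housekeeping gene used for normalisation (default
#'   "RPS20").
#' @param group_a,group_b the two group labels to compare.
#' @return one-row data.frame of class `relative_expression`: gene_id,
#'   mean dCt and SE per group, ddCt, ratio, se_ddct, p_value, n_a, n_b.
#' @export
delta_delta_ct <- function(ct_table, target, reference = "RPS20",
                           group_a, group_b) {
  needed <- c("sample_id", "group", "gene_id", "ct")
  stopifnot(all(needed %in% names(ct_table)))
  tab <- ct_table[ct_table$group %in% c(group_a, group_b), , drop = FALSE]
  per_sample_ct <- function(gene) {
    sub <- tab[tab$gene_id == gene, , drop = FALSE]
    agg <- tapply(sub$ct, sub$sample_id, mean)
    agg
  }
  ct_t <- per_sample_ct(target)
  ct_r <- per_sample_ct(reference)
  missing_ref <- setdiff(names(ct_t), names(ct_r))
  if (length(missing_ref)) {
    stop("sample(s) missing the reference gene ", reference, ": ",
         paste(missing_ref, collapse = ", "))
  }
  dct <- ct_t - ct_r[names(ct_t)]
  grp <- tab$group[match(names(dct), tab$sample_id)]
  da <- dct[grp == group_a]
  db <- dct[grp == group_b]
  if (!length(da) || !length(db)) {
    stop("both groups need at least one sample with the target gene")
  }
  ddct <- mean(da) - mean(db)
  se <- sqrt(stats::var(da) / length(da) + stats::var(db) / length(db))
  p <- if (length(da) > 1L && length(db) > 1L) {
    # degenerate (zero-variance) groups have no defined t statistic
    tryCatch(stats::t.test(da, db, var.equal = FALSE)$p.value,
             error = function(e) NA_real_)
  } else {
    NA_real_
  }
  out <- data.frame(gene_id = target,
                    mean_dct_a = mean(da), se_dct_a = stats::sd(da) /
                      sqrt(length(da)),
                    mean_dct_b = mean(db), se_dct_b = stats::sd(db) /
                      sqrt(length(db)),
                    ddct = ddct, ratio = 2^(-ddct), se_ddct = se,
                    p_value = p, n_a = length(da), n_b = length(db),
                    stringsAsFactors = FALSE)
  class(out) <- c("relative_expression", class(out))
  out
}

#' Quantify a panel of target genes
#'
#' Runs [delta_delta_ct()] for each target and stacks the results.
#'
#' @inheritParams delta_delta_ct
#' @param targets character vector of target genes.
#' @return data.frame, one row per target.
#' @export
qpcr_panel <- function(ct_table, targets, reference = "RPS20",
                       group_a, group_b) {
  out <- do.call(rbind, lapply(targets, function(g) {
    delta_delta_ct(ct_table, g, reference, group_a, group_b)
  }))
  rownames(out) <- NULL
  out
}

#' Side-by-side qPCR vs DGE concordance table
#'
#' Joins qPCR expression ratios with the DGE TPM ratios for the same
#' genes, on the same group_a-over-group_b orientation.
#'
#' @param qpcr data.frame from [qpcr_panel()].
#' @param de `de_result` data.frame from [call_de()] where library `a`
#'   corresponds to the qPCR group_a.
#' @return data.frame (gene_id, qpcr_ratio, qpcr_log2, dge_ratio,
#'   dge_log2, qpcr_p, dge_fdr).
#' @export
concordance_table <- function(qpcr, de) {
  i <- match(qpcr$gene_id, de$gene_id)
  data.frame(gene_id = qpcr$gene_id,
             qpcr_ratio = qpcr$ratio,
             qpcr_log2 = -qpcr$ddct,
             dge_ratio = de$tpm_a[i] / de$tpm_b[i],
             dge_log2 = de$log2fc[i],
             qpcr_p = qpcr$p_value,
             dge_fdr = de$fdr[i],
             stringsAsFactors = FALSE)
}
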