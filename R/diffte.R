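# Differential translation efficiency (DiffTE): TMM normalization of Ribo
# and RNA count tables, RPKM, per-pair TE, and moderated-t testing of log2
# TE between two groups.

#' Differential translation efficiency between two groups
#'
#' Ribo-seq and RNA-seq tables are TMM-normalized independently, converted
#' to RPKM, combined into per-pair TE (Ribo RPKM / RNA RPKM), log2
#' transformed and tested with [moderated_fit()]. Genes below the
#' minimum-count filter (summed over samples, per assay) are removed before
#' TE computation; genes masked in every pair are absent from the fit.
#' `logFC > 0` means higher TE in the second group.
#'
#' @param ribo_counts,rna_counts `CountTable`s sharing a gene set.
#' @param pairs data.frame with columns `ribo`, `rna` (sample ids) and
#'   `group` (two levels; the first level in factor order is group 1).
#' @param lengths Named vector gene -> length in nt.
#' @param lfc_thresh,p_thresh Hit thresholds.
#' @param min_count Minimum summed raw count per assay.
#' @param rna_floor RNA RPKM below which a gene is masked in a pair.
#' @return List: `result` (gene table with `logFC`, `t_mod`, `p_value`,
#'   `fdr`, `status` and per-group mean TE), `te` (the `TEMatrix`),
#'   `factors` (TMM factors per assay).
#' @export
diffte_run <- function(ribo_counts, rna_counts, pairs, lengths,
                       lfc_thresh = 1.5, p_thresh = 0.05,
                       min_count = 10L, rna_floor = 0.1) {
  if (!setequal(ribo_counts$gene_ids, rna_counts$gene_ids))
    stop("Ribo and RNA tables must share the same gene set")
  ord <- match(ribo_counts$gene_ids, rna_counts$gene_ids)
  rna_counts <- count_table(rna_counts$counts[ord, , drop = FALSE])
  if (!all(pairs$ribo %in% ribo_counts$sample_ids) ||
      !all(pairs$rna %in% rna_counts$sample_ids))
    stop("pair sample id(s) missing from the count tables")
  glev <- unique(pairs$group)
  if (length(glev) != 2L) stop("`pairs$group` must have exactly two levels")
  grp <- as.integer(factor(pairs$group, levels = glev))
  if (any(tabulate(grp, 2L) < 2L))
    warning("fewer than 2 replicate pairs in a group; variance relies on the prior")

  keep <- rowSums(ribo_counts$counts) >= min_count &
          rowSums(rna_counts$counts) >= min_count
  ribo <- count_table(ribo_counts$counts[keep, , drop = FALSE])
  rna <- count_table(rna_counts$counts[keep, , drop = FALSE])
  if (nrow(ribo$counts) == 0L) stop("no gene passes the minimum-count filter")

  f_ribo <- tmm_factors(ribo)
  f_rna <- tmm_factors(rna)
  ribo_rpkm <- rpkm(ribo, lengths, f_ribo)
  rna_rpkm <- rpkm(rna, lengths, f_rna)
  te <- translation_efficiency(ribo_rpkm, rna_rpkm, pairs, rna_floor)

  logm <- te$log2_te
  usable <- rowSums(is.finite(logm)) > 0L
  fit <- moderated_fit(logm[usable, , drop = FALSE], grp)
  hits <- classify_hits(fit, lfc_thresh, p_thresh)
  mean_te_1 <- rowMeans(te$te[usable, grp == 1L, drop = FALSE], na.rm = TRUE)
  mean_te_2 <- rowMeans(te$te[usable, grp == 2L, drop = FALSE], na.rm = TRUE)
  result <- cbind(hits,
                  data.table::data.table(mean_te_group1 = mean_te_1,
                                         mean_te_group2 = mean_te_2))
  list(result = result, te = te,
       factors = list(ribo = f_ribo, rna = f_rna))
}
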