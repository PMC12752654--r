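# Differential codon occupancy (DiffCO): expression-normalized ribosome
# density per codon identity at the E/P/A sites and the three codons
# downstream of A, compared between two conditions with the moderated-t
# engine.

DIFFCO_SITES <- c(E = -2L, P = -1L, A = 0L, A1 = 1L, A2 = 2L, A3 = 3L)

#' Per-gene per-codon A-site density tracks
#'
#' Triplet-phase filtering: only reads whose A-site falls in frame 0 of a
#' CDS contribute. The first and last `trim` codons of each gene are
#' excluded to avoid initiation/termination edge effects. Genes shorter
#' than `2 * trim + 6` codons are skipped (counted in the `n_skipped`
#' attribute).
#'
#' @param reads Read data.table.
#' @param features Feature data.table.
#' @param genome A `GenomeSeq` or named list of them.
#' @param rule A [offset_rule()].
#' @param trim Codons removed from each gene end.
#' @return data.table `gene_id`, `codon_idx` (0-based), `codon`, `density`
#'   over retained positions; attribute `codons` holds each retained gene's
#'   full codon vector.
#' @export
codon_density <- function(reads, features, genome, rule = offset_rule(),
                          trim = 15L) {
  if (inherits(genome, "GenomeSeq"))
    genome <- stats::setNames(list(genome), genome$seqid)
  cds <- features[features$ftype == "CDS", ]
  n_cod_all <- (cds$end - cds$start) %/% 3L
  usable <- n_cod_all >= 2L * trim + 6L
  n_skipped <- sum(!usable)
  cds <- cds[usable, ]
  if (nrow(cds) == 0L) stop("no gene long enough for trim = ", trim)

  pos <- assign_asite(reads, rule)
  hit <- locate_in_cds(pos, reads$seqid, reads$strand, cds, match_strand = TRUE)
  ok <- !is.na(hit)
  rel <- integer(sum(ok))
  hidx <- hit[ok]
  rel <- ifelse(cds$strand[hidx] == "+", pos[ok] - cds$start[hidx],
                cds$end[hidx] - 1L - pos[ok])
  frame0 <- rel %% 3L == 0L                       # triplet-phase filter
  hidx <- hidx[frame0]; cidx <- rel[frame0] %/% 3L

  codon_lists <- stats::setNames(vector("list", nrow(cds)), cds$gene_id)
  out <- vector("list", nrow(cds))
  for (i in seq_len(nrow(cds))) {
    row <- cds[i, ]
    codons <- gene_codon_types(genome[[row$seqid]], row)
    codon_lists[[row$gene_id]] <- codons
    n_cod <- length(codons)
    dens <- tabulate(cidx[hidx == i] + 1L, nbins = n_cod)
    keep <- (trim + 1L):(n_cod - trim)              # 1-based retained window
    out[[i]] <- data.table::data.table(gene_id = row$gene_id,
                                       codon_idx = keep - 1L,
                                       codon = codons[keep],
                                       density = dens[keep])
  }
  res <- data.table::rbindlist(out)
  data.table::setattr(res, "codons", codon_lists)
  data.table::setattr(res, "n_skipped", n_skipped)
  res
}

#' Site-specific codon occupancy for one sample
#'
#' For each retained position `j` with A-site density `d`, the codon read at
#' the chosen site is at `j-2` (E), `j-1` (P), `j` (A) or `j+1..j+3`
#' (A1..A3). The contribution is `d` divided by the gene's mean retained
#' per-codon density (controlling for expression level); occupancy of a
#' codon identity is the mean contribution over all positions carrying it.
#' Positions whose site index leaves the retained window are skipped, as
#' are genes with zero retained density. Stop codons are excluded.
#'
#' @param tracks Output of [codon_density()].
#' @param site One of E, P, A, A1, A2, A3.
#' @param downstream_window Optional integer W: normalize each position by
#'   the mean density over codons `j+4 .. j+4+W` instead of the gene mean.
#' @return Named numeric vector over the 61 sense codons (NA where a codon
#'   is never observed at the site).
#' @export
site_occupancy <- function(tracks, site = "A", downstream_window = NULL) {
  shift <- DIFFCO_SITES[[site]]
  codon_lists <- attr(tracks, "codons")
  contrib <- numeric(0); ctype <- character(0)
  for (gid in unique(tracks$gene_id)) {
    g <- tracks[tracks$gene_id == gid, ]
    if (all(g$density == 0L)) next
    codons <- codon_lists[[gid]]
    idx_min <- min(g$codon_idx); idx_max <- max(g$codon_idx)
    k <- g$codon_idx + shift
    ok <- k >= idx_min & k <= idx_max
    if (!any(ok)) next
    if (is.null(downstream_window)) {
      norm <- rep(mean(g$density), sum(ok))
    } else {
      norm <- vapply(g$codon_idx[ok], function(j) {
        win <- g$density[g$codon_idx >= j + 4L &
                         g$codon_idx <= j + 4L + downstream_window]
        if (length(win)) mean(win) else NA_real_
      }, numeric(1L))
    }
    val <- g$density[ok] / norm
    val[!is.finite(val)] <- NA_real_
    contrib <- c(contrib, val)
    ctype <- c(ctype, codons[k[ok] + 1L])
  }
  keep <- !is.na(contrib) & ctype %in% SENSE_CODONS
  agg <- tapply(contrib[keep], factor(ctype[keep], levels = SENSE_CODONS), mean)
  out <- as.numeric(agg)
  names(out) <- SENSE_CODONS
  out
}

#' Build a codon x sample occupancy matrix for one site
#'
#' @param read_sets Named list of read data.tables.
#' @param features,genome,rule,trim Passed to [codon_density()].
#' @inheritParams site_occupancy
#' @return 61 x n_samples numeric matrix.
#' @export
occupancy_matrix <- function(read_sets, features, genome,
                             rule = offset_rule(), site = "A", trim = 15L,
                             downstream_window = NULL) {
  cols <- lapply(read_sets, function(r) {
    tr <- codon_density(r, features, genome, rule, trim)
    site_occupancy(tr, site, downstream_window)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- names(read_sets)
  m
}

#' Differential codon occupancy between two conditions
#'
#' Per site: the log2 occupancy matrix (floored at `pseudo` before the log
#' to absorb zero occupancies of rare codons) goes through
#' [moderated_fit()] and [classify_hits()]. `logFC > 0` means higher
#' occupancy in the second group.
#'
#' @param group1,group2 Named lists of read data.tables (one per sample).
#' @param features,genome,rule,trim As in [codon_density()].
#' @param sites Sites to test.
#' @param lfc_thresh,p_thresh Hit thresholds.
#' @param pseudo Occupancy floor before the log transform.
#' @param downstream_window Passed to [site_occupancy()].
#' @return Named list (one entry per site) of data.tables: `codon`,
#'   `amino_acid`, `mean_occ_group1`, `mean_occ_group2`, `logFC`, `t_mod`,
#'   `p_value`, `fdr`, `status`.
#' @export
diffco_run <- function(group1, group2, features, genome,
                       rule = offset_rule(), sites = names(DIFFCO_SITES),
                       trim = 15L, lfc_thresh = 1.5, p_thresh = 0.05,
                       pseudo = 1e-3, downstream_window = NULL) {
  if (!length(group1) || !length(group2))
    stop("each condition needs at least one sample")
  if (is.null(names(group1))) names(group1) <- paste0("g1s", seq_along(group1))
  if (is.null(names(group2))) names(group2) <- paste0("g2s", seq_along(group2))
  read_sets <- c(group1, group2)
  groups <- rep(1:2, c(length(group1), length(group2)))
  aa <- Biostrings::GENETIC_CODE[SENSE_CODONS]
  out <- list()
  for (site in sites) {
    occ <- occupancy_matrix(read_sets, features, genome, rule, site, trim,
                            downstream_window)
    logm <- log2(pmax(occ, pseudo))
    logm[is.na(occ)] <- NA_real_
    fit <- moderated_fit(logm, groups)
    hits <- classify_hits(fit, lfc_thresh, p_thresh)
    tab <- data.table::data.table(
      codon = SENSE_CODONS,
      amino_acid = unname(aa),
      mean_occ_group1 = rowMeans(occ[, groups == 1L, drop = FALSE], na.rm = TRUE),
      mean_occ_group2 = rowMeans(occ[, groups == 2L, drop = FALSE], na.rm = TRUE))
    tab <- cbind(tab, hits[, c("logFC", "t_mod", "p_value", "fdr", "status")])
    out[[site]] <- tab
  }
  out
}
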