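# Footprint site assignment, periodicity and metagene diagnostics, gene
# counting, TMM normalization, RPKM and translation efficiency.

#' A-site offset rule
#'
#' Footprint A-sites are located by displacing a fixed anchor (the 3' end by
#' default, the bacterial convention) towards the read interior. The
#' returned position is the first base of the A-site codon in transcript
#' orientation.
#'
#' @param offset Default displacement in nt from the anchor to the first base
#'   of the A-site codon.
#' @param offset_by_length Optional named integer vector (read length ->
#'   displacement) overriding the default per length.
#' @param anchor `"three_prime"` or `"five_prime"`.
#' @return A `SiteOffsetRule` list.
#' @export
offset_rule <- function(offset = 11L, offset_by_length = integer(0),
                        anchor = c("three_prime", "five_prime")) {
  anchor <- match.arg(anchor)
  structure(list(anchor = anchor, offset = as.integer(offset),
                 offset_by_length = offset_by_length),
            class = "SiteOffsetRule")
}

rule_offsets <- function(rule, lengths) {
  off <- rep(rule$offset, length(lengths))
  if (length(rule$offset_by_length)) {
    hit <- match(as.character(lengths), names(rule$offset_by_length))
    off[!is.na(hit)] <- rule$offset_by_length[hit[!is.na(hit)]]
  }
  as.integer(off)
}

#' Assign the A-site position of each read
#'
#' Strand-aware: for minus-strand reads the anchor is mirrored. For a
#' three-prime rule with offset `o`, a plus-strand read yields
#' `left + length - 1 - o` and a minus-strand read `left + o`.
#'
#' @param reads Read data.table.
#' @param rule A [offset_rule()].
#' @return Integer vector of genomic A-site positions (0-based first base of
#'   the A-site codon in transcript orientation).
#' @export
assign_asite <- function(reads, rule = offset_rule()) {
  off <- rule_offsets(rule, reads$length)
  if (any(off < 0L | off >= reads$length))
    stop("offset falls outside the read span for length(s) ",
         paste(unique(reads$length[off < 0L | off >= reads$length]), collapse = ", "))
  if (rule$anchor == "three_prime") {
    ifelse(reads$strand == "+",
           reads$left + reads$length - 1L - off,
           reads$left + off)
  } else {
    ifelse(reads$strand == "+",
           reads$left + off,
           reads$left + reads$length - 1L - off)
  }
}

# Map genomic single-base positions to containing CDS rows, strand-matched
# when match_strand. Positions hitting more than one candidate CDS are
# dropped (counted in attr "n_ambiguous").
locate_in_cds <- function(pos, seqid, strand, cds, match_strand = TRUE) {
  gr_pos <- GenomicRanges::GRanges(seqid, IRanges::IRanges(pos + 1L, width = 1L),
                                   strand = if (match_strand) strand else "*")
  gr_cds <- GenomicRanges::GRanges(cds$seqid, IRanges::IRanges(cds$start + 1L, cds$end),
                                   strand = if (match_strand) cds$strand else "*")
  ov <- GenomicRanges::findOverlaps(gr_pos, gr_cds,
                                    ignore.strand = !match_strand)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  dup <- q %in% q[duplicated(q)]
  hit <- rep(NA_integer_, length(pos))
  hit[q[!dup]] <- s[!dup]
  attr(hit, "n_ambiguous") <- length(unique(q[dup]))
  hit
}

asite_frame <- function(pos, cds_row_start, cds_row_end, strand) {
  ifelse(strand == "+", (pos - cds_row_start) %% 3L,
         (cds_row_end - 1L - pos) %% 3L)
}

#' Calibrate the A-site offset from annotated CDS
#'
#' For each read length the displacement from the 3' anchor (searched over
#' `0..max_offset`) maximizing the fraction of assigned A-sites in frame 0 of
#' annotated CDS is chosen; ties go to the smallest displacement. When fewer
#' than `min_reads` footprints overlap CDS, or no displacement beats the
#' uniform baseline (frame-0 fraction < 0.45), the default rule is returned
#' with a warning.
#'
#' @param reads Read data.table.
#' @param features Feature data.table.
#' @param max_offset Largest displacement searched.
#' @param min_reads Minimum in-CDS footprints required.
#' @param default Fallback [offset_rule()].
#' @return A calibrated `SiteOffsetRule`.
#' @export
calibrate_offset <- function(reads, features, max_offset = 17L,
                             min_reads = 500L, default = offset_rule()) {
  cds <- features[features$ftype == "CDS", ]
  if (nrow(reads) < min_reads) {
    warning("fewer than ", min_reads, " reads; returning default offset rule")
    return(default)
  }
  lens <- sort(unique(reads$length))
  by_len <- integer(0)
  best_fracs <- numeric(0)
  for (L in lens) {
    sub <- reads[reads$length == L, ]
    fracs <- vapply(0:min(max_offset, L - 1L), function(d) {
      pos <- ifelse(sub$strand == "+", sub$left + L - 1L - d, sub$left + d)
      hit <- locate_in_cds(pos, sub$seqid, sub$strand, cds)
      ok <- !is.na(hit)
      if (!any(ok)) return(NA_real_)
      st <- cds$start[hit[ok]]; en <- cds$end[hit[ok]]
      fr <- asite_frame(pos[ok], st, en, sub$strand[ok])
      rel <- ifelse(sub$strand[ok] == "+", pos[ok] - st, en - 1L - pos[ok])
      sense <- rel < (en - st) - 3L      # decoding happens on sense codons,
      # never the stop; scoring over all reads of this length means shifts
      # that push A-sites off the coding span lose mass, which resolves the
      # mod-3 degeneracy of the frame criterion
      sum(fr == 0L & sense) / nrow(sub)
    }, numeric(1L))
    if (all(is.na(fracs))) next
    d_best <- which.max(fracs) - 1L          # ties -> smallest displacement
    by_len[as.character(L)] <- d_best
    best_fracs <- c(best_fracs, max(fracs, na.rm = TRUE))
  }
  n_incds <- sum(!is.na(locate_in_cds(assign_asite(reads, default),
                                      reads$seqid, reads$strand, cds)))
  if (length(by_len) == 0L || n_incds < min_reads) {
    warning("insufficient in-CDS reads for calibration; returning default rule")
    return(default)
  }
  if (max(best_fracs) < 0.45) {
    warning("no displacement shows triplet periodicity (best frame-0 fraction ",
            sprintf("%.2f", max(best_fracs)), "); returning default rule")
    return(default)
  }
  offset_rule(offset = default$offset, offset_by_length = by_len,
              anchor = default$anchor)
}

#' Frame distribution of A-sites over annotated CDS
#'
#' @param reads Read data.table.
#' @param features Feature data.table.
#' @param rule A [offset_rule()].
#' @return Numeric vector `c(f0, f1, f2)` summing to 1 over reads whose
#'   A-site falls inside a CDS.
#' @export
frame_distribution <- function(reads, features, rule = offset_rule()) {
  cds <- features[features$ftype == "CDS", ]
  pos <- assign_asite(reads, rule)
  hit <- locate_in_cds(pos, reads$seqid, reads$strand, cds)
  ok <- !is.na(hit)
  if (!any(ok)) stop("no A-sites fall inside annotated CDS")
  fr <- asite_frame(pos[ok], cds$start[hit[ok]], cds$end[hit[ok]], reads$strand[ok])
  as.numeric(table(factor(fr, levels = 0:2)) / sum(ok))
}

#' Metagene profile around the start codon
#'
#' A-site density is collected per gene at transcript-space offsets
#' `-upstream .. downstream-1` relative to the first base of the start
#' codon, each gene's covered profile is scaled to unit mean, genes are
#' averaged, and the result is rescaled so its mean over covered positions
#' is 1. Offsets beyond a gene's end are missing for that gene.
#'
#' @param reads Read data.table.
#' @param features Feature data.table.
#' @param rule A [offset_rule()].
#' @param upstream,downstream Window bounds in nt.
#' @return Numeric vector of length `upstream + downstream`, named by offset.
#' @export
metagene_profile <- function(reads, features, rule = offset_rule(),
                             upstream = 20L, downstream = 60L) {
  cds <- features[features$ftype == "CDS", ]
  glen <- cds$end - cds$start
  if (all(glen < downstream))
    stop("window extends past every gene; shrink `downstream`")
  pos <- assign_asite(reads, rule)
  hit <- locate_in_cds(pos, reads$seqid, reads$strand, cds, match_strand = TRUE)
  offsets <- (-upstream):(downstream - 1L)
  prof_sum <- numeric(length(offsets))
  n_cov <- numeric(length(offsets))
  for (i in seq_len(nrow(cds))) {
    covered <- offsets < glen[i]
    if (!any(covered)) next
    sel <- which(!is.na(hit) & hit == i)
    counts <- numeric(length(offsets))
    if (length(sel)) {
      rel <- if (cds$strand[i] == "+") pos[sel] - cds$start[i]
             else cds$end[i] - 1L - pos[sel]
      idx <- match(rel, offsets)
      tab <- table(idx[!is.na(idx)])
      counts[as.integer(names(tab))] <- as.numeric(tab)
    }
    m <- mean(counts[covered])
    if (m > 0) counts <- counts / m
    prof_sum[covered] <- prof_sum[covered] + counts[covered]
    n_cov[covered] <- n_cov[covered] + 1L
  }
  prof <- ifelse(n_cov > 0, prof_sum / n_cov, NA_real_)
  mu <- mean(prof, na.rm = TRUE)
  if (mu > 0) prof <- prof / mu
  names(prof) <- offsets
  prof
}

#' Count reads per gene for one sample
#'
#' Ribo-seq reads are counted by A-site-in-CDS (strand-matched); RNA-seq
#' reads by read-midpoint-in-CDS (strand ignored). Reads whose site falls in
#' more than one candidate CDS are discarded (reported in the
#' `n_ambiguous` attribute).
#'
#' @param reads Read data.table.
#' @param features Feature data.table.
#' @param assay `"ribo"` or `"rna"`.
#' @param rule A [offset_rule()] (ribo only).
#' @param sample_id Column name for the returned single-sample table.
#' @return A `CountTable` with one sample.
#' @export
gene_counts <- function(reads, features, assay = c("ribo", "rna"),
                        rule = offset_rule(), sample_id = "sample1") {
  assay <- match.arg(assay)
  cds <- features[features$ftype == "CDS", ]
  n <- integer(nrow(cds))
  n_amb <- 0L
  if (nrow(reads) > 0L) {
    if (assay == "ribo") {
      pos <- assign_asite(reads, rule)
      hit <- locate_in_cds(pos, reads$seqid, reads$strand, cds, match_strand = TRUE)
    } else {
      pos <- reads$left + reads$length %/% 2L
      hit <- locate_in_cds(pos, reads$seqid, reads$strand, cds, match_strand = FALSE)
    }
    n_amb <- attr(hit, "n_ambiguous")
    tab <- table(hit[!is.na(hit)])
    n[as.integer(names(tab))] <- as.integer(tab)
  }
  m <- matrix(n, ncol = 1L, dimnames = list(cds$gene_id, sample_id))
  out <- count_table(m)
  attr(out, "n_ambiguous") <- n_amb
  out
}

#' Build a multi-sample CountTable from several read sets
#'
#' @param read_sets Named list of read data.tables (names = sample ids).
#' @param features Feature data.table.
#' @inheritParams gene_counts
#' @return A `CountTable`.
#' @export
build_count_matrix <- function(read_sets, features, assay = c("ribo", "rna"),
                               rule = offset_rule()) {
  assay <- match.arg(assay)
  cols <- lapply(names(read_sets), function(s)
    gene_counts(read_sets[[s]], features, assay, rule, sample_id = s)$counts)
  count_table(do.call(cbind, cols))
}

#' TMM between-sample normalization factors
#'
#' Trimmed mean of M-values (30% of M, 5% of A trimmed, precision weights,
#' reference column chosen by the 75th-percentile rule), rescaled to
#' geometric mean 1.
#'
#' @param table A `CountTable` with at least two samples.
#' @return Named numeric vector of scaling factors.
#' @export
tmm_factors <- function(table) {
  m <- table$counts
  if (ncol(m) < 2L) stop("TMM needs at least two samples")
  if (any(colSums(m) == 0)) stop("sample(s) with zero total count")
  f <- edgeR::calcNormFactors(m, method = "TMM")
  names(f) <- colnames(m)
  f
}

#' RPKM with TMM-effective library sizes
#'
#' `rpkm[g,s] = count[g,s] * 1e9 / (length[g] * total[s] * factor[s])`.
#'
#' @param table A `CountTable`.
#' @param lengths Named numeric vector gene -> length in nt.
#' @param factors Per-sample scaling factors (default: TMM if >= 2 samples,
#'   else 1).
#' @return Numeric matrix, genes x samples.
#' @export
rpkm <- function(table, lengths,
                 factors = if (ncol(table$counts) >= 2L) tmm_factors(table)
                           else stats::setNames(1, colnames(table$counts))) {
  len <- lengths[table$gene_ids]
  if (anyNA(len)) stop("lengths missing for gene(s): ",
                       paste(table$gene_ids[is.na(len)][1:3], collapse = ", "))
  if (any(len <= 0)) stop("zero or negative gene length")
  eff <- colSums(table$counts) * factors[table$sample_ids]
  sweep(table$counts, 1L, len, "/") %*% diag(1e9 / eff, ncol(table$counts)) ->
    out
  dimnames(out) <- dimnames(table$counts)
  out
}

#' Translation efficiency per paired sample
#'
#' TE is the ratio of Ribo-seq RPKM to RNA-seq RPKM per gene and pair. Genes
#' whose RNA RPKM falls below `rna_floor` in a pair are masked (NA) rather
#' than producing unstable or infinite ratios.
#'
#' @param ribo_rpkm,rna_rpkm RPKM matrices sharing a gene set.
#' @param pairs data.frame with columns `ribo`, `rna` (sample ids) and
#'   optionally `pair_id`.
#' @param rna_floor RNA RPKM below which the gene is masked in that pair.
#' @return A `TEMatrix` list with `gene_ids`, `pairs`, `te`, `log2_te`.
#' @export
translation_efficiency <- function(ribo_rpkm, rna_rpkm, pairs, rna_floor = 0.1) {
  if (!identical(rownames(ribo_rpkm), rownames(rna_rpkm)))
    stop("ribo and rna matrices must share an identical gene set")
  if (!all(pairs$ribo %in% colnames(ribo_rpkm)) ||
      !all(pairs$rna %in% colnames(rna_rpkm)))
    stop("unpaired sample id(s) in `pairs`")
  if (is.null(pairs$pair_id)) pairs$pair_id <- paste0(pairs$ribo, "_vs_", pairs$rna)
  te <- matrix(NA_real_, nrow(ribo_rpkm), nrow(pairs),
               dimnames = list(rownames(ribo_rpkm), pairs$pair_id))
  for (k in seq_len(nrow(pairs))) {
    r <- ribo_rpkm[, pairs$ribo[k]]
    n <- rna_rpkm[, pairs$rna[k]]
    v <- r / n
    v[n < rna_floor] <- NA_real_
    te[, k] <- v
  }
  structure(list(gene_ids = rownames(te), pairs = pairs,
                 te = te, log2_te = log2(te)), class = "TEMatrix")
}
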