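# Candidate ORF enumeration, ORFscore periodicity scoring, sORF filtering
# and mass-spectrometry peptide cross-referencing.

#' Enumerate candidate ORFs
#'
#' Scans every reading frame for start codons (default ATG/GTG/TTG) paired
#' with the nearest in-frame stop (TAA/TAG/TGA). All starts sharing a stop
#' are emitted (nested starts resolved downstream); candidates are
#' deduplicated by (seqid, strand, start, end). `length_nt` counts the full
#' ORF including the stop codon.
#'
#' @param genome A `GenomeSeq` or named list of them.
#' @param starts Start codon set.
#' @param min_len,max_len ORF length bounds in nt (stop included);
#'   `min_len >= 9` (start, one codon, stop).
#' @param both_strands Scan the reverse strand too.
#' @return data.table: `seqid`, `strand`, `start` (0-based first base of the
#'   start codon), `end` (0-based exclusive past the stop), `start_codon`,
#'   `length_nt`, `protein`.
#' @export
enumerate_orfs <- function(genome, starts = START_CODONS, min_len = 9L,
                           max_len = Inf, both_strands = TRUE) {
  stopifnot(min_len >= 9L)
  if (inherits(genome, "GenomeSeq")) {
    genome <- stats::setNames(list(genome), genome$seqid)
  }
  out <- list()
  for (g in genome) {
    slen <- nchar(g$sequence)
    strands <- if (both_strands) c("+", "-") else "+"
    for (std in strands) {
      seq <- if (std == "+") g$sequence else revcomp(g$sequence)
      for (f in 0:2) {
        n_cod <- (slen - f) %/% 3L
        if (n_cod < 3L) next
        cpos <- f + 3L * (seq_len(n_cod) - 1L)        # 0-based codon starts
        cods <- substring(seq, cpos + 1L, cpos + 3L)
        s_idx <- which(cods %in% starts)
        e_idx <- which(cods %in% STOP_CODONS)
        if (!length(s_idx) || !length(e_idx)) next
        nxt <- e_idx[findInterval(s_idx, e_idx) + 1L]
        ok <- !is.na(nxt)
        s_idx <- s_idx[ok]; nxt <- nxt[ok]
        len <- 3L * (nxt - s_idx + 1L)
        keep <- len >= min_len & len <= max_len
        if (!any(keep)) next
        s_idx <- s_idx[keep]; nxt <- nxt[keep]; len <- len[keep]
        beg <- cpos[s_idx]                             # strand-local coords
        if (std == "+") {
          gstart <- beg; gend <- beg + len
        } else {
          gend <- slen - beg; gstart <- gend - len
        }
        out[[length(out) + 1L]] <- data.table::data.table(
          seqid = g$seqid, strand = std, start = gstart, end = gend,
          start_codon = cods[s_idx], length_nt = len)
      }
    }
  }
  if (!length(out)) {
    return(data.table::data.table(seqid = character(), strand = character(),
                                  start = integer(), end = integer(),
                                  start_codon = character(),
                                  length_nt = integer(), protein = character()))
  }
  orfs <- unique(data.table::rbindlist(out),
                 by = c("seqid", "strand", "start", "end"))
  orfs[, protein := vapply(seq_len(.N), function(i)
    translate_orf(orfs[i, ], genome), character(1L))]
  data.table::setorder(orfs, seqid, strand, start)
  orfs[]
}

#' Translate an ORF to protein
#'
#' Standard bacterial code; non-ATG initiators translate to M at position 1;
#' the stop codon is excluded.
#'
#' @param orf One candidate row (list or one-row data.table with `seqid`,
#'   `strand`, `start`, `end`).
#' @param genome A `GenomeSeq` or named list of them.
#' @return Amino-acid string.
#' @export
translate_orf <- function(orf, genome) {
  if (inherits(genome, "GenomeSeq")) {
    genome <- stats::setNames(list(genome), genome$seqid)
  }
  g <- genome[[orf$seqid]]
  seq <- substr(g$sequence, orf$start + 1L, orf$end)
  if (orf$strand == "-") seq <- revcomp(seq)
  body <- substr(seq, 1L, nchar(seq) - 3L)             # drop the stop
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(body),
                                           if.fuzzy.codon = "X"))
  if (grepl("\\*", aa)) stop("internal stop codon in ORF at ", orf$start)
  substr(aa, 1L, 1L) <- "M"                            # initiator convention
  aa
}

#' ORFscore from per-frame A-site counts
#'
#' With `Fbar = (F1 + F2 + F3) / 3`, the score is
#' `log2(1 + sum((Fi - Fbar)^2 / Fbar))`, negated when frame 1 is not
#' strictly the maximal frame, and 0 when all counts are 0.
#'
#' @param f1,f2,f3 A-site counts in the three frames of the ORF.
#' @return Signed ORFscore.
#' @export
orfscore_from_counts <- function(f1, f2, f3) {
  tot <- f1 + f2 + f3
  fbar <- tot / 3
  chi <- ifelse(tot == 0, 0, (f1 - fbar)^2 / fbar + (f2 - fbar)^2 / fbar +
                             (f3 - fbar)^2 / fbar)
  score <- log2(1 + chi)
  ifelse(tot == 0, 0, ifelse(f1 > f2 & f1 > f3, score, -score))
}

#' ORFscore of a candidate against footprint A-sites
#'
#' Counts A-sites (strand-matched) in the three frames of the ORF after
#' trimming `trim_codons` codons from each end, then applies
#' [orfscore_from_counts()].
#'
#' @param orf One candidate row.
#' @param reads Read data.table.
#' @param rule A [offset_rule()].
#' @param trim_codons Codons removed from each ORF end before counting.
#' @return List with `F1`, `F2`, `F3` and `orfscore`.
#' @export
orfscore <- function(orf, reads, rule = offset_rule(), trim_codons = 1L) {
  n_cod <- orf$length_nt %/% 3L
  if (n_cod - 2L * trim_codons < 3L)
    stop("ORF shorter than 3 codons after trimming")
  counts <- c(0, 0, 0)
  if (nrow(reads) > 0L) {
    sel <- reads$seqid == orf$seqid & reads$strand == orf$strand
    if (any(sel)) {
      pos <- assign_asite(reads[sel, ], rule)
      rel <- if (orf$strand == "+") pos - orf$start else orf$end - 1L - pos
      keep <- rel >= 3L * trim_codons & rel < orf$length_nt - 3L * trim_codons
      if (any(keep)) {
        fr <- rel[keep] %% 3L
        counts <- as.numeric(table(factor(fr, levels = 0:2)))
      }
    }
  }
  list(F1 = counts[1L], F2 = counts[2L], F3 = counts[3L],
       orfscore = orfscore_from_counts(counts[1L], counts[2L], counts[3L]))
}

#' Score every candidate ORF
#'
#' @param candidates Candidate data.table from [enumerate_orfs()].
#' @param reads Read data.table.
#' @inheritParams orfscore
#' @return The candidates with `F1`, `F2`, `F3`, `orfscore` columns.
#' @export
score_orfs <- function(candidates, reads, rule = offset_rule(),
                       trim_codons = 1L) {
  out <- data.table::copy(candidates)
  n <- nrow(out)
  F1 <- F2 <- F3 <- numeric(n)
  if (nrow(reads) > 0L && n > 0L) {
    pos_all <- assign_asite(reads, rule)
    # sorted A-site positions per (seqid, strand): per-ORF frame counts then
    # reduce to a binary search plus a tabulate over the in-window slice
    keys <- split(seq_len(nrow(reads)), paste(reads$seqid, reads$strand))
    sorted <- lapply(keys, function(ix) sort(pos_all[ix]))
    for (i in seq_len(n)) {
      sp <- sorted[[paste(out$seqid[i], out$strand[i])]]
      if (is.null(sp)) next
      t3 <- 3L * trim_codons
      lo <- out$start[i] + t3; hi <- out$end[i] - t3   # [lo, hi) window
      a <- findInterval(lo - 1L, sp) + 1L
      b <- findInterval(hi - 1L, sp)
      if (b < a) next
      rel <- if (out$strand[i] == "+") sp[a:b] - out$start[i]
             else out$end[i] - 1L - sp[a:b]
      cnt <- tabulate(rel %% 3L + 1L, nbins = 3L)
      F1[i] <- cnt[1L]; F2[i] <- cnt[2L]; F3[i] <- cnt[3L]
    }
  }
  out[, `:=`(F1 = F1, F2 = F2, F3 = F3,
             orfscore = orfscore_from_counts(F1, F2, F3))]
  out[]
}

#' Filter sORF candidates for downstream MS validation
#'
#' Keeps candidates shorter than `max_nt` (strict) with ORFscore strictly
#' greater than `min_score`.
#'
#' @param scored Candidate data.table with an `orfscore` column.
#' @param max_nt Length bound, nt.
#' @param min_score Score bound.
#' @return Filtered data.table; attribute `summary` holds the kept/total
#'   counts.
#' @export
filter_sorf_candidates <- function(scored, max_nt = 180L, min_score = 0) {
  keep <- scored$length_nt < max_nt & scored$orfscore > min_score
  out <- scored[keep, ]
  data.table::setattr(out, "summary",
                      c(total = nrow(scored), kept = sum(keep)))
  out
}

#' Cross-reference MS peptides with predicted proteins
#'
#' A peptide supports a protein iff it is an exact substring; with
#' `tryptic_check`, the residue preceding the match (if any) must be K or R
#' and the match must end at K/R or the protein terminus.
#'
#' @param proteins Named character vector (id -> amino-acid sequence).
#' @param peptides Character vector of peptides.
#' @param tryptic_check Enforce tryptic boundaries.
#' @return data.table `id`, `peptide` with one row per supported match.
#' @export
match_peptides <- function(proteins, peptides, tryptic_check = FALSE) {
  out <- list()
  for (id in names(proteins)) {
    prot <- proteins[[id]]
    for (pep in peptides) {
      hits <- gregexpr(pep, prot, fixed = TRUE)[[1L]]
      if (hits[1L] == -1L) next
      ok <- FALSE
      for (h in hits) {
        if (!tryptic_check) { ok <- TRUE; break }
        before <- if (h == 1L) "" else substr(prot, h - 1L, h - 1L)
        last <- substr(prot, h + nchar(pep) - 1L, h + nchar(pep) - 1L)
        at_end <- h + nchar(pep) - 1L == nchar(prot)
        if ((before == "" || before %in% c("K", "R")) &&
            (at_end || last %in% c("K", "R"))) { ok <- TRUE; break }
      }
      if (ok) out[[length(out) + 1L]] <-
          data.table::data.table(id = id, peptide = pep)
    }
  }
  if (!length(out)) return(data.table::data.table(id = character(),
                                                  peptide = character()))
  data.table::rbindlist(out)
}
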