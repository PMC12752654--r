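# Readers/writers for the standard formats the toolkit touches.
#
# Coordinate convention: everything internal is 0-based half-open; GFF3 and
# SAM stay 1-based at the file boundary, converted exactly once here.

FOOTPRINT_MIN_LEN <- 18L
FOOTPRINT_MAX_LEN <- 40L

#' Read a genome FASTA
#'
#' Sequences are upper-cased and RNA bases (U) are mapped to T. Any character
#' outside \{A,C,G,T,N\} is an error.
#'
#' @param path Path to a FASTA file.
#' @return A named list of `GenomeSeq` objects, each a list with `seqid`,
#'   `sequence` and `circular` (always `FALSE` on read).
#' @export
read_genome <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("illegal character(s) in FASTA record(s): ",
         paste(names(set)[bad], collapse = ", "))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate seqids in ", path)
  out <- lapply(seq_along(ids), function(i) {
    genome_seq(ids[i], seqs[[i]])
  })
  names(out) <- ids
  out
}

#' Construct a GenomeSeq
#'
#' @param seqid Sequence identifier.
#' @param sequence DNA string over A/C/G/T/N.
#' @param circular Whether the replicon is circular.
#' @return A `GenomeSeq` list.
#' @export
genome_seq <- function(seqid, sequence, circular = FALSE) {
  stopifnot(nzchar(sequence), !grepl("[^ACGTN]", sequence))
  structure(list(seqid = seqid, sequence = sequence, circular = circular),
            class = "GenomeSeq")
}

#' Read CDS/gene features from a GFF3 file
#'
#' Returns a data.table of features with internal 0-based half-open
#' coordinates. CDS records whose length is not divisible by 3 are dropped
#' with a warning naming the offending gene ids.
#'
#' @param path Path to a GFF3 file.
#' @return data.table with columns `seqid`, `start` (0-based), `end`
#'   (exclusive), `strand`, `ftype`, `gene_id`.
#' @export
read_annotation <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% c("gene", "CDS")]
  md <- S4Vectors::mcols(gr)
  gene_id <- if ("gene_id" %in% names(md)) as.character(md$gene_id) else NA_character_
  for (alt in c("ID", "Parent", "locus_tag")) {
    if (alt %in% names(md)) {
      fallback <- vapply(md[[alt]], function(x) {
        if (length(x) == 0L || is.na(x[1L])) NA_character_ else as.character(x[1L])
      }, character(1L))
      gene_id <- ifelse(is.na(gene_id), fallback, gene_id)
    }
  }
  if (anyNA(gene_id)) stop("feature(s) without a gene identifier attribute in ", path)
  feats <- data.table::data.table(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,        # 1-based inclusive -> 0-based
    end = GenomicRanges::end(gr),                 # inclusive -> exclusive
    strand = as.character(GenomicRanges::strand(gr)),
    ftype = as.character(gr$type),
    gene_id = gene_id
  )
  if (any(feats$strand == "*")) stop("unstranded feature(s) in ", path)
  bad <- feats$ftype == "CDS" & (feats$end - feats$start) %% 3L != 0L
  if (any(bad)) {
    warning("dropping CDS with length not divisible by 3: ",
            paste(unique(feats$gene_id[bad]), collapse = ", "))
    feats <- feats[!bad]
  }
  feats[]
}

#' Write features to GFF3
#'
#' @param features Feature data.table (0-based half-open internal coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(features, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tribotranskit\t%s\t%d\t%d\t.\t%s\t%s\tID=%s;gene_id=%s",
                     features$seqid, features$ftype,
                     features$start + 1L, features$end,
                     features$strand,
                     ifelse(features$ftype == "CDS", "0", "."),
                     paste0(features$gene_id, ifelse(features$ftype == "CDS", ".cds", "")),
                     features$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read aligned reads from SAM/BAM
#'
#' Only primary, mapped records are consumed. The CIGAR is reduced to the
#' aligned reference span. Reads outside the 18-40 nt footprint window are
#' flagged (`in_footprint_window`) but not dropped; filtering is the caller's
#' decision.
#'
#' @param path SAM or BAM file.
#' @param genome Optional genome list (from [read_genome()]); when given,
#'   reference names absent from it are an error and origin-spanning reads on
#'   circular replicons are rejected.
#' @return data.table with `read_id`, `seqid`, `left` (0-based leftmost),
#'   `length` (reference span, nt), `strand`, `in_footprint_window`.
#' @export
read_alignments <- function(path, genome = NULL) {
  stopifnot(file.exists(path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(flag = flag,
                               what = c("qname", "rname", "pos", "cigar", "strand"))
  res <- Rsamtools::scanBam(bam, param = p)[[1L]]
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar)
  reads <- data.table::data.table(
    read_id = res$qname,
    seqid = as.character(res$rname),
    left = res$pos - 1L,                     # SAM 1-based -> 0-based
    length = as.integer(width),
    strand = as.character(res$strand)
  )
  reads[, in_footprint_window :=
          length >= FOOTPRINT_MIN_LEN & length <= FOOTPRINT_MAX_LEN]
  if (!is.null(genome)) {
    known <- names(genome)
    if (!all(reads$seqid %in% known)) {
      stop("alignment reference(s) absent from genome set: ",
           paste(setdiff(unique(reads$seqid), known), collapse = ", "))
    }
    lens <- vapply(genome, function(g) nchar(g$sequence), integer(1L))
    over <- reads$left + reads$length > lens[reads$seqid]
    if (any(over)) {
      stop("read(s) extend past the reference end (origin-spanning reads ",
           "are not supported): ", paste(reads$read_id[which(over)[1:min(3, sum(over))]],
                                         collapse = ", "))
    }
  }
  reads[]
}

#' Write aligned reads as SAM
#'
#' Emits match-only CIGAR records with sequences sliced from the genome
#' (reverse-complemented for minus-strand reads).
#'
#' @param reads Read data.table as returned by [read_alignments()].
#' @param genome Genome list used for the `@SQ` header and the SEQ field.
#' @param path Output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           vapply(genome, function(g)
             sprintf("@SQ\tSN:%s\tLN:%d", g$seqid, nchar(g$sequence)),
             character(1L)))
  if (nrow(reads) > 0L) {
    seqs <- vapply(seq_len(nrow(reads)), function(i) {
      g <- genome[[reads$seqid[i]]]
      s <- substr(g$sequence, reads$left[i] + 1L, reads$left[i] + reads$length[i])
      if (reads$strand[i] == "-") s <- revcomp(s)
      s
    }, character(1L))
    body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                    reads$read_id,
                    ifelse(reads$strand == "-", 16L, 0L),
                    reads$seqid,
                    reads$left + 1L,
                    reads$length,
                    seqs)
  } else body <- character(0L)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a TSV count table
#'
#' First column gene id, header row = sample ids.
#'
#' @param path TSV path.
#' @return A `CountTable`: list with `gene_ids`, `sample_ids`, `counts`
#'   (integer matrix, genes x samples).
#' @export
read_count_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1, with = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(dt[[1L]])
  count_table(m)
}

#' Construct a CountTable from a matrix
#'
#' @param counts Non-negative integer matrix with gene rownames and sample
#'   colnames.
#' @return A `CountTable` list.
#' @export
count_table <- function(counts) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)), !is.null(colnames(counts)))
  if (any(counts < 0)) stop("negative counts")
  structure(list(gene_ids = rownames(counts), sample_ids = colnames(counts),
                 counts = counts), class = "CountTable")
}

#' Write a CountTable as TSV
#' @param table A `CountTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  dt <- data.table::data.table(gene_id = table$gene_ids)
  dt <- cbind(dt, data.table::as.data.table(table$counts))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a peptide list (one peptide per line, optional source column)
#'
#' @param path TSV path; a `peptide` column is used when a header is present,
#'   otherwise the first column.
#' @param min_len Minimum peptide length retained.
#' @return Character vector of upper-case peptides.
#' @export
read_peptides <- function(path, min_len = 5L) {
  dt <- data.table::fread(path, sep = "\t", header = "auto")
  col <- if ("peptide" %in% names(dt)) dt$peptide else dt[[1L]]
  pep <- toupper(as.character(col))
  if (any(grepl("[^ACDEFGHIKLMNPQRSTVWY]", pep))) {
    stop("peptide(s) outside the 20-letter amino-acid alphabet in ", path)
  }
  pep[nchar(pep) >= min_len]
}

#' Reverse complement of a DNA string
#' @param x DNA string.
#' @return The reverse complement.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
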