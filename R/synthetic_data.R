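# Seeded generator of bacterial genomes, CDS annotations and Ribo-/RNA-seq
# alignments with planted translation-efficiency shifts and codon pauses.
#
# Model: per-gene read counts are Poisson; footprint A-site codons are
# multinomial over the gene's sense codons weighted by condition-specific
# pause factors; the A-site frame is 0 with probability frame0_prob, else 1
# or 2 uniformly. Footprint ends are placed deterministically from the
# sampled A-site, read length and the 3' anchor offset, so site assignment
# with the matching rule recovers the intended A-site exactly.

STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")

SENSE_CODONS <- local({
  nt <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(nt, nt, paste0), nt, paste0))
  sort(setdiff(all, STOP_CODONS))
})

#' Simulation configuration
#'
#' @param n_genes Number of genes.
#' @param gene_len_range Gene length range in codons, start and stop included
#'   (an sORF is a gene shorter than 100 codons, i.e. < 300 nt).
#' @param sorf_fraction Fraction of genes planted as sORFs.
#' @param intergenic_len Intergenic spacer length, nt (>= 40 so footprints
#'   anchored near gene ends stay on the reference).
#' @param frame0_prob Probability a footprint's A-site lands in frame 0.
#' @param read_len_range Footprint length range, nt (within 18-40).
#' @param depth_per_gene Mean footprints per gene at rate 1.
#' @param asite_offset 3' anchor offset used to place footprint ends, nt.
#' @param conditions Condition labels.
#' @param pause_map Named list condition -> named numeric vector
#'   (codon -> multiplicative A-site dwell factor); unlisted codons are 1.
#' @param te_multipliers Named list condition -> named numeric vector
#'   (gene_id -> translation-rate factor); unlisted genes are 1.
#' @param tx_rates Named numeric vector gene_id -> transcription rate
#'   (unlisted genes 1); shared by conditions so TE shifts are purely
#'   translational.
#' @param rna_depth Mean RNA-seq reads per gene at rate 1 (defaults to
#'   `depth_per_gene`).
#' @param rng_seed Integer seed governing every generator.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_genes = 50L,
                       gene_len_range = c(60L, 250L),
                       sorf_fraction = 0.3,
                       intergenic_len = 100L,
                       frame0_prob = 0.85,
                       read_len_range = c(24L, 32L),
                       depth_per_gene = 200,
                       asite_offset = 11L,
                       conditions = NULL,
                       pause_map = list(),
                       te_multipliers = list(),
                       tx_rates = numeric(0),
                       rna_depth = NULL,
                       rng_seed = 1L) {
  if (is.null(conditions)) {
    conditions <- union(names(pause_map), names(te_multipliers))
    if (!length(conditions)) conditions <- c("A", "B")
  }
  cfg <- list(n_genes = as.integer(n_genes),
              gene_len_range = as.integer(gene_len_range),
              sorf_fraction = sorf_fraction,
              intergenic_len = as.integer(intergenic_len),
              frame0_prob = frame0_prob,
              read_len_range = as.integer(read_len_range),
              depth_per_gene = depth_per_gene,
              asite_offset = as.integer(asite_offset),
              conditions = conditions,
              pause_map = pause_map,
              te_multipliers = te_multipliers,
              tx_rates = tx_rates,
              rna_depth = if (is.null(rna_depth)) depth_per_gene else rna_depth,
              rng_seed = as.integer(rng_seed))
  validate_sim_config(cfg)
  structure(cfg, class = "SimConfig")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 1L) stop("config error: n_genes must be >= 1")
    if (gene_len_range[1L] < 2L) stop("config error: genes need at least 2 codons")
    if (gene_len_range[1L] > gene_len_range[2L]) stop("config error: bad gene_len_range")
    if (sorf_fraction < 0 || sorf_fraction > 1) stop("config error: sorf_fraction in [0,1]")
    if (sorf_fraction > 0 && gene_len_range[1L] >= 100L)
      stop("config error: sorf_fraction > 0 needs gene_len_range min < 100 codons")
    if (sorf_fraction < 1 && gene_len_range[2L] < 100L)
      stop("config error: sorf_fraction < 1 needs gene_len_range max >= 100 codons")
    if (frame0_prob <= 0 || frame0_prob > 1) stop("config error: frame0_prob in (0,1]")
    if (read_len_range[1L] < 18L || read_len_range[2L] > 40L ||
        read_len_range[1L] > read_len_range[2L])
      stop("config error: read lengths must lie in 18-40")
    if (intergenic_len < 40L) stop("config error: intergenic_len must be >= 40")
    for (pm in pause_map) if (any(pm <= 0)) stop("config error: pause factors must be > 0")
    for (tm in te_multipliers) if (any(tm <= 0)) stop("config error: te factors must be > 0")
  })
  invisible(cfg)
}

# Run expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# sample() treats a length-1 vector as 1:n; this keeps degenerate ranges safe
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

random_cds <- function(n_codons) {
  start <- sample(START_CODONS, 1L, prob = c(0.80, 0.12, 0.08))
  body <- sample(SENSE_CODONS, n_codons - 2L, replace = TRUE)
  stop <- sample(STOP_CODONS, 1L)
  paste0(start, paste(body, collapse = ""), stop)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Build a synthetic genome with planted sORFs
#'
#' Genes are laid out left to right on a single replicon with intergenic
#' spacers, alternating randomly between strands. Each CDS starts with
#' ATG/GTG/TTG, ends with a stop codon and contains no in-frame internal
#' stop. Deterministic for a fixed `rng_seed`.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (a GenomeSeq), `features` (gene + CDS
#'   data.table, 0-based half-open) and `truth` (per-gene data.table with
#'   `is_sorf`, `tx_rate` and one `te_<condition>` column per condition).
#' @export
build_genome <- function(config) {
  validate_sim_config(config)
  with_seed(config$rng_seed, {
    n <- config$n_genes
    n_sorf <- round(config$sorf_fraction * n)
    is_sorf <- rep(FALSE, n)
    if (n_sorf > 0L) is_sorf[sample.int(n, n_sorf)] <- TRUE
    lo <- config$gene_len_range[1L]; hi <- config$gene_len_range[2L]
    len_codons <- integer(n)
    for (i in seq_len(n)) {
      len_codons[i] <- if (is_sorf[i]) resample(lo:min(99L, hi), 1L)
                       else resample(max(100L, lo):hi, 1L)
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    gene_id <- sprintf("g%04d", seq_len(n))

    pieces <- character(2L * n + 1L)
    pieces[1L] <- random_dna(config$intergenic_len)
    pos <- config$intergenic_len
    start <- integer(n); end <- integer(n)
    for (i in seq_len(n)) {
      cds <- random_cds(len_codons[i])
      if (strand[i] == "-") cds <- revcomp(cds)
      start[i] <- pos
      end[i] <- pos + nchar(cds)
      pieces[2L * i] <- cds
      pieces[2L * i + 1L] <- random_dna(config$intergenic_len)
      pos <- end[i] + config$intergenic_len
    }
    genome <- genome_seq("chrSim", paste(pieces, collapse = ""))

    cds <- data.table::data.table(seqid = "chrSim", start = start, end = end,
                                  strand = strand, ftype = "CDS", gene_id = gene_id)
    genes <- data.table::copy(cds)[, ftype := "gene"]
    features <- rbind(genes, cds)

    tx <- rep(1, n); names(tx) <- gene_id
    if (length(config$tx_rates)) {
      hit <- intersect(names(config$tx_rates), gene_id)
      tx[hit] <- config$tx_rates[hit]
    }
    truth <- data.table::data.table(gene_id = gene_id, strand = strand,
                                    length_nt = 3L * len_codons,
                                    n_codons = len_codons,
                                    is_sorf = is_sorf, tx_rate = tx)
    for (cond in config$conditions) {
      te <- rep(1, n); names(te) <- gene_id
      tm <- config$te_multipliers[[cond]]
      if (!is.null(tm)) {
        hit <- intersect(names(tm), gene_id)
        te[hit] <- tm[hit]
      }
      truth[, (paste0("te_", cond)) := te]
    }
    list(genome = genome, features = features, truth = truth)
  })
}

gene_codon_types <- function(genome, feat_row) {
  s <- feat_row$start; e <- feat_row$end
  seq <- substr(genome$sequence, s + 1L, e)
  if (feat_row$strand == "-") seq <- revcomp(seq)
  n <- nchar(seq) %/% 3L
  substring(seq, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
}

# Genomic coordinate of the first (transcript-space) base of codon j, frame f.
transcript_to_genomic <- function(feat_row, offset_nt) {
  if (feat_row$strand == "+") feat_row$start + offset_nt
  else feat_row$end - 1L - offset_nt
}

#' Simulate ribosome footprints for one condition
#'
#' @param genome GenomeSeq from [build_genome()].
#' @param features Feature data.table (CDS rows are used).
#' @param config The [sim_config()].
#' @param condition Condition label (must be in `config$conditions`).
#' @param seed Seed for this draw; defaults to `config$rng_seed`.
#' @return Read data.table (`read_id`, `seqid`, `left`, `length`, `strand`)
#'   plus hidden truth columns `true_asite` (genomic first base of the
#'   intended A-site codon) and `true_frame`.
#' @export
simulate_ribo_reads <- function(genome, features, config, condition,
                                seed = config$rng_seed) {
  if (!condition %in% config$conditions)
    stop("unknown condition: ", condition)
  cds <- features[features$ftype == "CDS", ]
  pm <- config$pause_map[[condition]]
  with_seed(seed, {
    out <- vector("list", nrow(cds))
    for (i in seq_len(nrow(cds))) {
      row <- cds[i, ]
      te <- 1
      tm <- config$te_multipliers[[condition]]
      if (!is.null(tm) && row$gene_id %in% names(tm)) te <- tm[[row$gene_id]]
      tx <- 1
      if (length(config$tx_rates) && row$gene_id %in% names(config$tx_rates))
        tx <- config$tx_rates[[row$gene_id]]
      n_reads <- stats::rpois(1L, config$depth_per_gene * te * tx)
      if (n_reads == 0L) next
      codons <- gene_codon_types(genome, row)
      sense_idx <- seq_len(length(codons) - 1L)      # A-site never on the stop
      w <- rep(1, length(sense_idx))
      if (!is.null(pm)) {
        hit <- match(codons[sense_idx], names(pm))
        w[!is.na(hit)] <- pm[hit[!is.na(hit)]]
      }
      j <- resample(sense_idx, n_reads, replace = TRUE, prob = w) - 1L
      f <- ifelse(stats::runif(n_reads) < config$frame0_prob, 0L,
                  sample(1:2, n_reads, replace = TRUE))
      len <- resample(config$read_len_range[1L]:config$read_len_range[2L],
                      n_reads, replace = TRUE)
      p <- transcript_to_genomic(row, 3L * j + f)
      left <- if (row$strand == "+") p - len + 1L + config$asite_offset
              else p - config$asite_offset
      out[[i]] <- data.table::data.table(
        read_id = sprintf("%s_%s_fp%06d", row$gene_id, condition, seq_len(n_reads)),
        seqid = row$seqid, left = as.integer(left), length = len,
        strand = row$strand, true_asite = as.integer(p), true_frame = f)
    }
    res <- data.table::rbindlist(out)
    if (nrow(res) == 0L)
      res <- data.table::data.table(read_id = character(), seqid = character(),
                                    left = integer(), length = integer(),
                                    strand = character(), true_asite = integer(),
                                    true_frame = integer())
    res[]
  })
}

#' Simulate RNA-seq reads for one condition
#'
#' Reads are uniform along each gene; per-gene counts follow the
#' transcription rate only, so between-condition TE differences in the
#' matched Ribo-seq libraries are purely translational.
#'
#' @inheritParams simulate_ribo_reads
#' @return Read data.table.
#' @export
simulate_rna_reads <- function(genome, features, config, condition,
                               seed = config$rng_seed + 10000L) {
  if (!condition %in% config$conditions)
    stop("unknown condition: ", condition)
  cds <- features[features$ftype == "CDS", ]
  with_seed(seed, {
    out <- vector("list", nrow(cds))
    for (i in seq_len(nrow(cds))) {
      row <- cds[i, ]
      tx <- 1
      if (length(config$tx_rates) && row$gene_id %in% names(config$tx_rates))
        tx <- config$tx_rates[[row$gene_id]]
      n_reads <- stats::rpois(1L, config$rna_depth * tx)
      if (n_reads == 0L) next
      len <- resample(config$read_len_range[1L]:config$read_len_range[2L],
                      n_reads, replace = TRUE)
      len <- pmin(len, row$end - row$start)
      left <- row$start +
        floor(stats::runif(n_reads) * (row$end - row$start - len + 1L))
      out[[i]] <- data.table::data.table(
        read_id = sprintf("%s_%s_rna%06d", row$gene_id, condition, seq_len(n_reads)),
        seqid = row$seqid, left = as.integer(left), length = as.integer(len),
        strand = row$strand)
    }
    res <- data.table::rbindlist(out)
    if (nrow(res) == 0L)
      res <- data.table::data.table(read_id = character(), seqid = character(),
                                    left = integer(), length = integer(),
                                    strand = character())
    res[]
  })
}

#' Write a complete benchmark bundle to disk
#'
#' Emits the genome FASTA, annotation GFF3, one SAM per condition x assay x
#' replicate, and the truth table TSV. Byte-identical across runs with the
#' same config.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @param n_reps Replicates per condition and assay.
#' @return List with `files` (named paths), `truth`, `genome`, `features`.
#' @export
make_benchmark_bundle <- function(config, out_dir, n_reps = 2L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- build_genome(config)
  genome <- list(sim$genome); names(genome) <- sim$genome$seqid
  files <- c(fasta = file.path(out_dir, "genome.fa"),
             gff = file.path(out_dir, "annotation.gff3"),
             truth = file.path(out_dir, "truth.tsv"))
  writeLines(c(paste0(">", sim$genome$seqid), sim$genome$sequence), files[["fasta"]])
  write_annotation(sim$features, files[["gff"]])
  data.table::fwrite(sim$truth, files[["truth"]], sep = "\t")
  k <- 0L
  for (cond in config$conditions) {
    for (rep_i in seq_len(n_reps)) {
      k <- k + 1L
      seed <- config$rng_seed + 1000L * k
      ribo <- simulate_ribo_reads(sim$genome, sim$features, config, cond, seed = seed)
      rna <- simulate_rna_reads(sim$genome, sim$features, config, cond,
                                seed = seed + 500L)
      fr <- file.path(out_dir, sprintf("ribo_%s_rep%d.sam", cond, rep_i))
      fn <- file.path(out_dir, sprintf("rna_%s_rep%d.sam", cond, rep_i))
      write_sam(ribo, genome, fr)
      write_sam(rna, genome, fn)
      files[[sprintf("ribo_%s_rep%d", cond, rep_i)]] <- fr
      files[[sprintf("rna_%s_rep%d", cond, rep_i)]] <- fn
    }
  }
  list(files = files, truth = sim$truth, genome = sim$genome,
       features = sim$features)
}
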