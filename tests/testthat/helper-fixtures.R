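# Shared fixtures and independent oracles. Everything is generated in code;
# heavier objects are memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

rtk_ns <- asNamespace("ribotranskit")

# Small two-condition simulation shared by several tests.
tiny_sim <- function() memo("tiny_sim", {
  cfg <- sim_config(n_genes = 20L, depth_per_gene = 300, rng_seed = 42L)
  sim <- build_genome(cfg)
  list(cfg = cfg, sim = sim,
       ribo = simulate_ribo_reads(sim$genome, sim$features, cfg, "A"),
       rna = simulate_rna_reads(sim$genome, sim$features, cfg, "A"))
})

random_reads <- function(genome, n, seed, len_range = 24:32) {
  set.seed(seed)
  data.table::data.table(
    read_id = sprintf("r%05d", seq_len(n)),
    seqid = genome$seqid,
    left = sample.int(nchar(genome$sequence) - 40L, n, replace = TRUE) - 1L,
    length = sample(len_range, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE))
}

# ---- independent oracles ---------------------------------------------------

# Straightforward TMM re-implementation (no shortcuts): Robinson-Oshlack
# weighted trimmed mean of M-values against a reference column.
naive_tmm <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  lib <- colSums(counts)
  q75 <- apply(counts, 2L, function(x) stats::quantile(x / sum(x), 0.75))
  ref <- which.min(abs(q75 - mean(q75)))
  f <- numeric(ncol(counts))
  for (s in seq_len(ncol(counts))) {
    obs <- counts[, s] / lib[s]
    rf <- counts[, ref] / lib[ref]
    keep <- obs > 0 & rf > 0
    M <- log2(obs[keep] / rf[keep])
    A <- (log2(obs[keep]) + log2(rf[keep])) / 2
    w <- (1 - obs[keep]) / (counts[keep, s]) + (1 - rf[keep]) / (counts[keep, ref])
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
    tr <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    f[s] <- if (max(abs(M)) < 1e-6) 1 else 2^(sum(M[tr] / w[tr]) / sum(1 / w[tr]))
  }
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# Pairwise-concordance ROC-AUC: P(score_pos > score_neg) + 0.5 P(tie).
auc_pairwise <- function(labels, scores) {
  sp <- scores[labels == 1L]; sn <- scores[labels == 0L]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# Character-by-character six-frame ORF scan, independent of enumerate_orfs.
brute_orf_scan <- function(seq, starts = c("ATG", "GTG", "TTG"),
                           min_len = 9L) {
  stops <- c("TAA", "TAG", "TGA")
  revcomp_chr <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1L]]), collapse = "")
  }
  out <- list()
  for (std in c("+", "-")) {
    s <- if (std == "+") seq else revcomp_chr(seq)
    n <- nchar(s)
    for (i in seq_len(n - 2L)) {
      cod <- substr(s, i, i + 2L)
      if (!cod %in% starts) next
      j <- i + 3L
      while (j + 2L <= n) {
        cj <- substr(s, j, j + 2L)
        if (cj %in% stops) {
          len <- j + 3L - i
          if (len >= min_len) {
            if (std == "+") { gs <- i - 1L; ge <- i - 1L + len }
            else { ge <- n - i + 1L; gs <- ge - len }
            out[[length(out) + 1L]] <- data.frame(strand = std, start = gs,
                                                  end = ge, length_nt = len)
          }
          break
        }
        j <- j + 3L
      }
    }
  }
  if (!length(out)) return(data.frame(strand = character(), start = integer(),
                                      end = integer(), length_nt = integer()))
  unique(do.call(rbind, out))
}

# ---- model fixtures --------------------------------------------------------

# TIS fragments with a planted Shine-Dalgarno-like 8-mer upstream of
# positives; negatives are CTG-centred random context.
make_tis_fixture <- function(n_pos, n_neg, seed, shuffle_labels = FALSE) {
  rtk_ns$with_seed(seed, {
    rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
    pos <- replicate(n_pos, {
      up <- rnd(50); substr(up, 36, 43) <- "AGGAGGTA"
      paste0(up, "ATG", rnd(20))
    })
    neg <- replicate(n_neg, paste0(rnd(50), "CTG", rnd(20)))
    lab <- rep(c(1L, 0L), c(n_pos, n_neg))
    if (shuffle_labels) lab <- sample(lab)
    data.table::data.table(fragment = c(pos, neg), label = lab)
  })
}

# ORF windows with Poisson-sampled triplet-periodic coverage (frame-0 share
# 0.9) for class 1 and flat coverage for class 0.
make_ribo_fixture <- function(n_pos, n_neg, window_nt, depth_per_codon,
                              seed) {
  rtk_ns$with_seed(seed, {
    rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
    shares <- rep(c(0.9, 0.05, 0.05) * depth_per_codon, length.out = window_nt)
    flat <- rep(depth_per_codon / 3, window_nt)
    norm <- function(v) if (mean(v) > 0) v / mean(v) else v
    rows <- list()
    for (i in seq_len(n_pos)) rows[[length(rows) + 1L]] <-
      data.table::data.table(id = paste0("p", i),
                             sequence = paste0("ATG", rnd(window_nt - 6L), "TAA"),
                             class_label = 1L, neg_kind = "",
                             coverage = list(norm(stats::rpois(window_nt, shares))))
    for (i in seq_len(n_neg)) rows[[length(rows) + 1L]] <-
      data.table::data.table(id = paste0("n", i), sequence = rnd(window_nt),
                             class_label = 0L, neg_kind = "flat",
                             coverage = list(norm(stats::rpois(window_nt, flat))))
    data.table::rbindlist(rows)
  })
}

small_model_config <- function(...) {
  args <- list(conv_channels = c(32L, 32L), d_model = 32L, heads = 4L,
               n_transformer = 1L, stem_channels = 8L, n_residual = 1L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(model_config, args)
}
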