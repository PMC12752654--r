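test_that("invalid configurations are rejected", {
  expect_error(sim_config(gene_len_range = c(1L, 50L)), "2 codons")
  expect_error(sim_config(frame0_prob = 0), "frame0_prob")
  expect_error(sim_config(read_len_range = c(10L, 32L)), "18-40")
  expect_error(sim_config(sorf_fraction = 1, gene_len_range = c(120L, 200L)),
               "min < 100")
  expect_error(sim_config(pause_map = list(A = c(CCG = -1), B = c())),
               "pause factors")
})

test_that("genome construction is seeded-deterministic and honours sorf_fraction", {
  cfg <- sim_config(n_genes = 10L, sorf_fraction = 0.5, rng_seed = 7L)
  a <- build_genome(cfg)
  b <- build_genome(cfg)
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(a$truth, b$truth)
  expect_equal(sum(a$truth$is_sorf), 5L)
  expect_true(all(a$truth$n_codons[a$truth$is_sorf] < 100L))
  expect_true(all(a$truth$n_codons[!a$truth$is_sorf] >= 100L))

  cfg0 <- sim_config(n_genes = 8L, sorf_fraction = 0, rng_seed = 3L)
  expect_true(all(build_genome(cfg0)$truth$n_codons >= 100L))
})

test_that("every simulated CDS translates without internal stops", {
  fx <- tiny_sim()
  cds <- fx$sim$features[fx$sim$features$ftype == "CDS", ]
  for (i in seq_len(nrow(cds))) {
    prot <- translate_orf(cds[i, ], fx$sim$genome)
    expect_false(grepl("\\*", prot))
    expect_equal(nchar(prot), (cds$end[i] - cds$start[i]) / 3 - 1)
  }
})

test_that("footprint placement lets the matching offset rule recover every A-site", {
  fx <- tiny_sim()
  pos <- assign_asite(fx$ribo, offset_rule(11L))
  expect_true(all(pos == fx$ribo$true_asite))
})

test_that("planted pause factors shape empirical A-site density", {
  ratios <- vapply(1:3, function(s) {
    cfg <- sim_config(n_genes = 10L, gene_len_range = c(100L, 150L),
                      sorf_fraction = 0, depth_per_gene = 400,
                      frame0_prob = 1, rng_seed = s,
                      pause_map = list(A = c(CCG = 5), B = c()))
    sim <- build_genome(cfg)
    reads <- simulate_ribo_reads(sim$genome, sim$features, cfg, "A")
    cds <- sim$features[sim$features$ftype == "CDS", ]
    num <- den <- c(0, 0)
    for (i in seq_len(nrow(cds))) {
      codons <- rtk_ns$gene_codon_types(sim$genome, cds[i, ])
      sense <- seq_len(length(codons) - 1L)
      sel <- reads[reads$true_asite >= cds$start[i] &
                   reads$true_asite < cds$end[i] &
                   reads$strand == cds$strand[i], ]
      rel <- if (cds$strand[i] == "+") sel$true_asite - cds$start[i]
             else cds$end[i] - 1L - sel$true_asite
      cnt <- tabulate(rel %/% 3L + 1L, nbins = length(codons))
      is_ccg <- codons[sense] == "CCG"
      num <- num + c(sum(cnt[sense][is_ccg]), sum(is_ccg))
      den <- den + c(sum(cnt[sense][!is_ccg]), sum(!is_ccg))
    }
    (num[1] / num[2]) / (den[1] / den[2])
  }, numeric(1L))
  expect_true(abs(mean(ratios) - 5) / 5 < 0.15)
})

test_that("RNA reads are uniform along genes and depth 0 gives none", {
  cfg <- sim_config(n_genes = 2L, gene_len_range = c(200L, 250L),
                    sorf_fraction = 0, depth_per_gene = 2000, rng_seed = 5L)
  sim <- build_genome(cfg)
  rna <- simulate_rna_reads(sim$genome, sim$features, cfg, "A")
  cds <- sim$features[sim$features$ftype == "CDS", ][1L, ]
  mids <- rna[rna$left >= cds$start & rna$left < cds$end, ]
  mid <- mids$left + mids$length %/% 2L
  bins <- cut(mid, breaks = seq(cds$start, cds$end, length.out = 11L))
  p <- stats::chisq.test(table(bins))$p.value
  expect_gt(p, 0.01)

  cfg0 <- sim_config(n_genes = 3L, depth_per_gene = 0, rng_seed = 1L)
  sim0 <- build_genome(cfg0)
  expect_equal(nrow(simulate_ribo_reads(sim0$genome, sim0$features, cfg0, "A")), 0L)
  expect_error(simulate_ribo_reads(sim0$genome, sim0$features, cfg0, "C"),
               "unknown condition")
})

test_that("benchmark bundles write the full file set byte-identically", {
  cfg <- sim_config(n_genes = 6L, depth_per_gene = 30, rng_seed = 9L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- make_benchmark_bundle(cfg, d1)
  b2 <- make_benchmark_bundle(cfg, d2)
  # 1 FASTA + 1 GFF3 + truth + 2 cond x 2 assays x 2 reps = 8 SAM
  expect_length(b1$files, 11L)
  expect_true(all(file.exists(unlist(b1$files))))
  for (k in names(b1$files)) {
    expect_identical(readLines(b1$files[[k]]), readLines(b2$files[[k]]),
                     info = k)
  }
  expect_equal(sort(b1$truth$gene_id), sprintf("g%04d", 1:6))
  expect_equal(anyDuplicated(b1$truth$gene_id), 0L)
})
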