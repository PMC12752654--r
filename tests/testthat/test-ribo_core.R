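test_that("A-site assignment follows the 3' anchor arithmetic on both strands", {
  reads <- data.table::data.table(read_id = c("a", "b"), seqid = "chr",
                                  left = c(100L, 100L), length = c(30L, 30L),
                                  strand = c("+", "-"))
  rule <- offset_rule(11L)
  expect_equal(assign_asite(reads, rule), c(100 + 30 - 1 - 11, 100 + 11))
  bad <- data.table::data.table(read_id = "c", seqid = "chr", left = 0L,
                                length = 20L, strand = "+")
  expect_error(assign_asite(bad, offset_rule(25L)), "outside the read span")
})

test_that("offset calibration recovers the planted displacement per length", {
  fx <- tiny_sim()
  rule <- calibrate_offset(fx$ribo, fx$sim$features)
  expect_true(all(rule$offset_by_length == 11L))
  expect_setequal(names(rule$offset_by_length), as.character(24:32))
})

test_that("calibration falls back with a warning on aperiodic or sparse reads", {
  fx <- tiny_sim()
  rand <- random_reads(fx$sim$genome, 2000L, seed = 1L)
  expect_warning(r <- calibrate_offset(rand, fx$sim$features),
                 "periodicity")
  expect_length(r$offset_by_length, 0L)
  expect_warning(r2 <- calibrate_offset(fx$ribo[1:10, ], fx$sim$features),
                 "default")
  expect_length(r2$offset_by_length, 0L)
})

test_that("frame distribution matches the simulated periodicity", {
  fx <- tiny_sim()
  fd <- frame_distribution(fx$ribo, fx$sim$features)
  expect_equal(sum(fd), 1)
  se <- sqrt(0.85 * 0.15 / nrow(fx$ribo))
  expect_lt(abs(fd[1L] - 0.85), 5 * se + 0.01)

  cfg1 <- sim_config(n_genes = 10L, frame0_prob = 1, depth_per_gene = 100,
                     rng_seed = 2L)
  s1 <- build_genome(cfg1)
  r1 <- simulate_ribo_reads(s1$genome, s1$features, cfg1, "A")
  expect_equal(frame_distribution(r1, s1$features), c(1, 0, 0))

  cfg3 <- sim_config(n_genes = 10L, frame0_prob = 1 / 3,
                     depth_per_gene = 500, rng_seed = 3L)
  s3 <- build_genome(cfg3)
  r3 <- simulate_ribo_reads(s3$genome, s3$features, cfg3, "A")
  fd3 <- frame_distribution(r3, s3$features)
  expect_true(all(abs(fd3 - 1 / 3) < 0.03))
})

test_that("metagene profile is flat at 1 under uniform density", {
  cfg <- sim_config(n_genes = 15L, frame0_prob = 1 / 3, depth_per_gene = 800,
                    gene_len_range = c(100L, 150L), sorf_fraction = 0,
                    rng_seed = 8L)
  sim <- build_genome(cfg)
  reads <- simulate_ribo_reads(sim$genome, sim$features, cfg, "A")
  prof <- metagene_profile(reads, sim$features, upstream = 0L,
                           downstream = 90L)
  expect_equal(mean(prof, na.rm = TRUE), 1, tolerance = 1e-8)
  expect_lt(stats::sd(prof, na.rm = TRUE), 0.25)
  expect_error(metagene_profile(reads, sim$features, downstream = 10000L),
               "past every gene")
})

test_that("gene counting assigns by A-site (ribo) and midpoint (rna)", {
  fx <- tiny_sim()
  ct <- gene_counts(fx$ribo, fx$sim$features, "ribo")
  expect_equal(sum(ct$counts), nrow(fx$ribo))   # every read lands in its gene
  per_gene <- table(sub("_A_fp.*", "", fx$ribo$read_id))
  expect_equal(as.integer(ct$counts[names(per_gene), 1L]),
               as.integer(per_gene))
  ctr <- gene_counts(fx$rna, fx$sim$features, "rna")
  expect_equal(sum(ctr$counts), nrow(fx$rna))
  empty <- fx$ribo[0L, ]
  expect_true(all(gene_counts(empty, fx$sim$features, "ribo")$counts == 0L))
})

test_that("TMM factors match an independent re-implementation", {
  set.seed(11)
  for (rep_i in 1:5) {
    m <- matrix(stats::rnbinom(50 * 4, mu = 80 * stats::rlnorm(50), size = 5),
                50, 4, dimnames = list(sprintf("g%02d", 1:50),
                                       sprintf("s%d", 1:4)))
    m[1:5, 3] <- m[1:5, 3] * 8L   # asymmetric perturbation
    tab <- count_table(m)
    expect_equal(unname(tmm_factors(tab)), unname(naive_tmm(m)),
                 tolerance = 1e-10)
  }
})

test_that("TMM on proportional columns and permutation invariance", {
  m <- matrix(c(10L, 20L, 30L, 40L, 50L,
                20L, 40L, 60L, 80L, 100L), 5, 2,
              dimnames = list(sprintf("g%d", 1:5), c("s1", "s2")))
  f <- tmm_factors(count_table(m))
  # proportional columns: all M-values 0 after library-size accounting
  expect_equal(unname(f), c(1, 1), tolerance = 1e-12)
  expect_equal(prod(f), 1, tolerance = 1e-12)

  set.seed(2)
  m2 <- matrix(stats::rpois(100 * 3, 50), 100, 3,
               dimnames = list(sprintf("g%03d", 1:100), c("a", "b", "c")))
  perm <- sample.int(100)
  expect_equal(unname(tmm_factors(count_table(m2))),
               unname(tmm_factors(count_table(m2[perm, ]))))
  expect_error(tmm_factors(count_table(m[, 1, drop = FALSE])), "two samples")
  m0 <- m; m0[, 2] <- 0L
  expect_error(tmm_factors(count_table(m0)), "zero total")
})

test_that("RPKM follows the formula and is scale-invariant per sample", {
  m <- matrix(c(100L, 900L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  # pad library to 1e6 via a filler gene
  m2 <- rbind(m, filler = 1e6L - 1000L)
  r <- rpkm(count_table(m2), c(g1 = 1000, g2 = 1000, filler = 1e6),
            factors = c(s1 = 1))
  expect_equal(unname(r["g1", 1L]), 100)

  tab <- count_table(m2)
  r2 <- rpkm(count_table(m2 * 2L), c(g1 = 1000, g2 = 1000, filler = 1e6),
             factors = c(s1 = 1))
  expect_equal(r2, r)
  expect_error(rpkm(tab, c(g1 = 0, g2 = 10, filler = 10), c(s1 = 1)),
               "length")
})

test_that("TE is the ribo/rna RPKM ratio with low-RNA masking", {
  rr <- matrix(c(20, 10, 5), 3, 1, dimnames = list(c("g1", "g2", "g3"), "r1"))
  nr <- matrix(c(10, 10, 0.01), 3, 1, dimnames = list(c("g1", "g2", "g3"), "n1"))
  te <- translation_efficiency(rr, nr, data.frame(ribo = "r1", rna = "n1"))
  expect_equal(unname(te$te["g1", 1L]), 2)
  expect_equal(unname(te$log2_te["g1", 1L]), 1)
  expect_equal(unname(te$te["g2", 1L]), 1)
  expect_equal(unname(te$log2_te["g2", 1L]), 0)
  expect_true(is.na(te$te["g3", 1L]))           # masked, not infinite
  expect_error(translation_efficiency(rr, nr,
                                      data.frame(ribo = "rX", rna = "n1")),
               "unpaired")
})
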