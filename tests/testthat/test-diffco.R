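# Helper building a synthetic density track directly, to oracle-test the
# occupancy arithmetic without the simulator in the loop.
manual_track <- function(codons, density, trim = 15L) {
  n <- length(codons)
  keep <- (trim + 1L):(n - trim)
  tr <- data.table::data.table(gene_id = "g1", codon_idx = keep - 1L,
                               codon = codons[keep], density = density[keep])
  data.table::setattr(tr, "codons", list(g1 = codons))
  tr
}

test_that("trim arithmetic retains the interior window and frame-1 reads drop", {
  cfg <- sim_config(n_genes = 4L, gene_len_range = c(100L, 100L),
                    sorf_fraction = 0, depth_per_gene = 200, frame0_prob = 1,
                    rng_seed = 6L)
  sim <- build_genome(cfg)
  reads <- simulate_ribo_reads(sim$genome, sim$features, cfg, "A")
  tr <- codon_density(reads, sim$features, sim$genome)
  # 100 codons, trim 15 -> codons 16..85 retained (70 positions, 0-based 15..84)
  expect_equal(sort(unique(tr$codon_idx)), 15:84)
  expect_equal(nrow(tr), 4L * 70L)

  # frame0_prob = 1 fixture: total retained density equals reads whose
  # A-site codon index falls in the retained window
  cds <- sim$features[sim$features$ftype == "CDS", ]
  n_in <- 0L
  for (i in seq_len(nrow(cds))) {
    sel <- reads[reads$strand == cds$strand[i] &
                 reads$true_asite >= cds$start[i] &
                 reads$true_asite < cds$end[i], ]
    rel <- if (cds$strand[i] == "+") sel$true_asite - cds$start[i]
           else cds$end[i] - 1L - sel$true_asite
    n_in <- n_in + sum(rel %/% 3L >= 15L & rel %/% 3L <= 84L)
  }
  expect_equal(sum(tr$density), n_in)

  # shift every read by +1 nt: all A-sites land in frame 1 and contribute 0
  shifted <- data.table::copy(reads)
  shifted[, left := left + 1L]
  tr1 <- codon_density(shifted, sim$features, sim$genome)
  expect_equal(sum(tr1$density), 0L)
})

test_that("uniform density yields occupancy exactly 1 for every codon", {
  set.seed(12)
  codons <- c("ATG", sample(rtk_ns$SENSE_CODONS, 98L, TRUE), "TAA")
  tr <- manual_track(codons, rep(7L, 100L))
  occ <- site_occupancy(tr, "A")
  seen <- unique(codons[16:85])
  expect_true(all(abs(occ[seen] - 1) < 1e-6))
  expect_true(all(is.na(occ[setdiff(names(occ), seen)])))
})

test_that("hand-computed mean-normalized occupancy for a planted pause codon", {
  # retained window of 70 codons: 7 CCG (10%) at density 3, 63 others at 1
  body <- rep("AAA", 100L)
  ccg_at <- 15L + seq(5L, 65L, by = 10L)          # 7 retained positions
  body[ccg_at + 1L] <- "CCG"
  body[1L] <- "ATG"; body[100L] <- "TAA"
  dens <- rep(1L, 100L); dens[ccg_at + 1L] <- 3L
  occ <- site_occupancy(manual_track(body, dens), "A")
  expect_equal(unname(occ["CCG"]), 3 / 1.2, tolerance = 1e-10)   # 2.5
  expect_equal(unname(occ["AAA"]), 1 / 1.2, tolerance = 1e-10)   # 0.8333

  # genomic-frequency-weighted mean over codon types is 1 at site A
  w <- table(body[16:85])
  expect_equal(sum(occ[names(w)] * as.numeric(w)) / sum(w), 1,
               tolerance = 1e-10)
})

test_that("site lookups shift the codon index by the ribosome geometry", {
  body <- rep("AAA", 100L)
  k <- 50L                                         # spike position (0-based)
  body[k + 1L] <- "CCG"                            # A-site codon X
  body[k] <- "GGG"                                 # codon at k-1 (P site)
  body[k - 1L] <- "TTT"                            # codon at k-2 (E site)
  body[1L] <- "ATG"; body[100L] <- "TAA"
  dens <- rep(1L, 100L); dens[k + 1L] <- 9L
  tr <- manual_track(body, dens)
  occ_a <- site_occupancy(tr, "A")
  occ_p <- site_occupancy(tr, "P")
  occ_e <- site_occupancy(tr, "E")
  expect_gt(occ_a["CCG"], 5)
  expect_gt(occ_p["GGG"], 5)                       # spike maps to codon at j-1
  expect_gt(occ_e["TTT"], 5)                       # and j-2 for E
  expect_lt(occ_p["CCG"], 1.2)                     # not smeared onto X itself
  expect_lt(occ_e["CCG"], 1.2)
})

test_that("differential testing flags the planted pause at the right site and direction", {
  cfg <- sim_config(n_genes = 15L, gene_len_range = c(100L, 180L),
                    sorf_fraction = 0, depth_per_gene = 500, frame0_prob = 1,
                    rng_seed = 21L, pause_map = list(A = c(CCG = 5), B = c()))
  sim <- build_genome(cfg)
  g1 <- lapply(1:2, function(i)
    simulate_ribo_reads(sim$genome, sim$features, cfg, "A", seed = 300L + i))
  g2 <- lapply(1:2, function(i)
    simulate_ribo_reads(sim$genome, sim$features, cfg, "B", seed = 400L + i))
  res <- diffco_run(g1, g2, sim$features, sim$genome, sites = c("A", "E"))
  a <- res$A
  expect_equal(nrow(a), 61L)                       # sense codons only
  expect_false(any(c("TAA", "TAG", "TGA") %in% a$codon))
  expect_equal(a[a$codon == "CCG", ]$status, "down")  # higher in condition 1
  expect_equal(res$E[res$E$codon == "CCG", ]$status, "ns")
  # identical conditions: no hits
  res0 <- diffco_run(g2[1], g2[2], sim$features, sim$genome, sites = "A")
  expect_equal(sum(res0$A$status != "ns"), 0L)
})
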