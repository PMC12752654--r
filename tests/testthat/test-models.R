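test_that("one-hot encoding maps ACGT to unit columns and N to zeros", {
  m <- one_hot("ACGT")
  expect_equal(unname(m), diag(4))
  expect_equal(unname(one_hot("N")), matrix(0, 4, 1))
  # argmax decoding round-trips
  seq <- "GATTACCA"
  m2 <- one_hot(seq)
  expect_equal(paste(rownames(m2)[apply(m2, 2L, which.max)], collapse = ""),
               seq)
  expect_equal(colSums(one_hot("ACGTN")), c(1, 1, 1, 1, 0),
               ignore_attr = TRUE)
})

test_that("scaled dot-product attention follows the softmax formula", {
  # identical keys: output is the mean of V rows
  K <- rbind(c(1, 0), c(1, 0))
  V <- rbind(c(2, 4), c(6, 8))
  out <- attention(matrix(c(5, 3), 1), K, V)
  expect_equal(unname(out), matrix(c(4, 6), 1), tolerance = 1e-12)

  # single key/value: output is that V row regardless of Q
  expect_equal(unname(attention(matrix(c(9, -9), 1), matrix(c(1, 1), 1),
                                matrix(c(3, 7), 1))),
               matrix(c(3, 7), 1))

  # hand-computed 2x2 case
  out2 <- attention(matrix(c(1, 0), 1), diag(2), diag(2), d_k = 2)
  w1 <- exp(1 / sqrt(2)) / (exp(1 / sqrt(2)) + 1)
  expect_equal(unname(out2), matrix(c(w1, 1 - w1), 1), tolerance = 1e-10)
  expect_equal(unname(round(out2, 3)), matrix(c(0.670, 0.330), 1),
               tolerance = 1e-3)

  # convexity: rows of the output lie in the convex hull of V rows
  set.seed(8)
  Q <- matrix(stats::rnorm(12), 4, 3); K <- matrix(stats::rnorm(15), 5, 3)
  V <- matrix(stats::runif(10), 5, 2)
  out3 <- attention(Q, K, V)
  expect_true(all(out3 >= min(V) - 1e-12 & out3 <= max(V) + 1e-12))
  expect_error(attention(Q, K, V, d_k = 0), "positive")
})

test_that("TIS fragments use the 50/3/20 geometry and CTG negatives", {
  fx <- tiny_sim()
  cfg <- model_config(rng_seed = 3L)
  ex <- extract_tis_fragments(fx$sim$genome, fx$sim$features, cfg)
  expect_true(all(nchar(ex$fragment) == 73L))
  expect_true(all(substr(ex$fragment, 51, 53) == ex$codon))
  expect_true(all(ex$codon[ex$label == 1L] %in% c("ATG", "GTG", "TTG")))
  expect_true(all(ex$codon[ex$label == 0L] == "CTG"))
  expect_setequal(unique(ex$split), c("train", "val", "test"))

  # plus-strand positive at position p spans [p-50, p+23)
  p1 <- ex[ex$label == 1L & ex$strand == "+", ][1L, ]
  expect_equal(p1$fragment,
               substr(fx$sim$genome$sequence, p1$pos - 50L + 1L, p1$pos + 23L))

  # a start too close to the sequence boundary is skipped
  small <- genome_seq("s", strrep("A", 80))
  feats <- data.table::data.table(seqid = "s", start = 10L, end = 70L,
                                  strand = "+", ftype = "CDS", gene_id = "g")
  # start at 10 lacks the 50 nt upstream flank; no CTG present either
  expect_equal(nrow(suppressWarnings(
    extract_tis_fragments(small, feats, cfg))), 0L)
  expect_error(extract_tis_fragments(genome_seq("s", "ACGT"), feats, cfg),
               "shorter")
})

test_that("ORF example construction respects the negative ratio and labeling", {
  fx <- tiny_sim()
  cfg <- model_config(window_nt = 303L, neg_ratio = 2, rng_seed = 5L)
  ex <- build_orf_examples(fx$sim$genome, fx$sim$features, fx$ribo,
                           offset_rule(), cfg)
  n_pos <- sum(ex$class_label == 1L)
  n_neg <- sum(ex$class_label == 0L)
  expect_equal(n_pos, 20L)                     # every gene has coverage
  expect_equal(n_neg, 40L)                     # neg:pos = 2
  expect_true(all(lengths(ex$coverage) == 303L))
  expect_setequal(unique(ex$neg_kind[ex$class_label == 0L]),
                  c("revcomp", "frameshift1", "frameshift2"))
  # positive coverage is normalized to unit mean over the window
  covs <- ex$coverage[ex$class_label == 1L]
  expect_true(all(abs(vapply(covs, mean, numeric(1L)) - 1) < 1e-9))
  # a read-free dataset has no positives
  expect_error(build_orf_examples(fx$sim$genome, fx$sim$features,
                                  fx$ribo[0L, ], offset_rule(), cfg),
               "coverage threshold")
})

test_that("classification metrics match pairwise-concordance and worked cases", {
  expect_equal(eval_classification(c(1, 1, 0, 0),
                                   c(0.9, 0.8, 0.3, 0.1))$roc_auc, 1)
  expect_equal(eval_classification(c(1, 1, 0, 0),
                                   c(0.8, 0.4, 0.6, 0.2))$roc_auc, 0.75)
  expect_equal(eval_classification(c(1, 0, 1, 0),
                                   rep(0.5, 4))$roc_auc, 0.5)
  expect_error(eval_classification(c(1, 1), c(0.2, 0.3)), "single-class")

  set.seed(14)
  for (i in 1:30) {
    n <- sample(10:200, 1L)
    labels <- stats::rbinom(n, 1L, 0.4)
    if (length(unique(labels)) < 2L) next
    scores <- round(stats::runif(n), sample(1:3, 1L))   # force ties
    expect_equal(eval_classification(labels, scores)$roc_auc,
                 auc_pairwise(labels, scores), tolerance = 1e-10)
  }
})

test_that("regression metrics follow the MSE/MAE definitions", {
  expect_equal(eval_regression(1:3, 1:3)$mse, 0)
  expect_equal(eval_regression(1:3, 1:3)$mae, 0)
  r <- eval_regression(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$mse, 1)
  expect_equal(r$mae, 1)
  expect_equal(eval_regression(c(1, 2, 3), c(2, 4, 6))$pearson_r, 1)
  expect_true(is.na(eval_regression(c(1, 2, 3), c(5, 5, 5))$pearson_r))
  expect_error(eval_regression(numeric(0), numeric(0)), "empty")
})

test_that("training is seed-reproducible and the loss decreases early", {
  ex <- make_tis_fixture(60L, 120L, seed = 9L)
  cfg <- small_model_config(epochs = 3L, lr = 3e-3, batch_size = 32L,
                            rng_seed = 9L)
  ex[, split := rtk_ns$assign_splits(.N, cfg$split, cfg$rng_seed)]
  m1 <- train_sorfpred(ex, cfg)
  m2 <- train_sorfpred(ex, cfg)
  expect_identical(m1$report, m2$report)
  expect_lt(m1$report$loss[3L], m1$report$loss[1L])
  solo <- data.table::copy(ex)[, label := 1L]
  expect_error(train_sorfpred(solo, cfg), "single class")
})

test_that("the sORF report bounds are strict on length and probability", {
  cfg <- small_model_config(window_nt = 60L, upsample = 3L, rng_seed = 2L)
  net <- rtk_ns$with_seed(2L, rtk_ns$build_sorfpredribo_net(cfg))
  model <- structure(list(net = net, config = cfg, report = NULL),
                     class = "sorfpredribo_model")
  cand <- data.table::data.table(
    id = c("a", "b", "c"),
    sequence = rep(strrep("A", 60L), 3L),
    coverage = rep(list(rep(1, 60L)), 3L),
    length_nt = c(299L, 300L, 150L))
  res <- predict_sorfpredribo(model, cand)
  expect_setequal(res$sorf$id, c("a", "c"))          # < 300 strict
  expect_true(all(res$high_confidence$probability > 0.99))
  # forcing probabilities confirms the 0.99 bound is strict
  res$sorf$probability <- c(0.995, 0.99)
  hc <- res$sorf[res$sorf$probability > 0.99, ]
  expect_equal(hc$id, "a")
})

test_that("fine-tuning from pretrained weights beats a cold start", {
  W <- 90L
  pool <- rbind(make_ribo_fixture(30L, 60L, W, 100, seed = 31L),
                make_ribo_fixture(30L, 60L, W, 100, seed = 32L))
  target <- make_ribo_fixture(30L, 60L, W, 100, seed = 33L)
  cfg_pre <- small_model_config(d_model = 16L, heads = 2L, upsample = 3L,
                                window_nt = W, epochs = 8L, lr = 5e-3,
                                batch_size = 32L, rng_seed = 31L)
  pool[, split := rtk_ns$assign_splits(.N, cfg_pre$split, cfg_pre$rng_seed)]
  pre <- train_sorfpredribo(pool, cfg_pre)

  cfg_ft <- small_model_config(d_model = 16L, heads = 2L, upsample = 3L,
                               window_nt = W, epochs = 3L, lr = 5e-3,
                               batch_size = 32L, rng_seed = 33L)
  target[, split := rtk_ns$assign_splits(.N, cfg_ft$split, cfg_ft$rng_seed)]
  warm <- train_sorfpredribo(target, cfg_ft, init = pre)
  cold <- train_sorfpredribo(target, cfg_ft)
  expect_lt(warm$report$loss[3L], cold$report$loss[3L])
})
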