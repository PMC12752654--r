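# The two sORF prediction models and their dataset-construction and
# evaluation machinery.
#
# sORFPred: sequence-only classifier of translation-initiation-site (TIS)
# context. Positives are 73-nt fragments (50 nt upstream + the codon +
# 20 nt downstream) around annotated ATG/GTG/TTG starts; negatives are CTG
# occurrences with the same flank geometry. CNN stem -> positional encoding
# -> Transformer encoder -> pooled sigmoid head.
#
# sORFPredRibo: multimodal classifier/regressor over candidate ORF windows
# pairing one-hot sequence with per-base footprint coverage. Per-modality
# conv stems -> concatenation -> residual blocks -> downsampling ->
# Transformer encoder -> (a) pooled classification head, (b) upsampling
# decoder restoring the input length for coverage regression. Loss =
# cross-entropy + lambda * MSE.

#' Model configuration
#'
#' @param conv_channels Channels of the two sORFPred conv blocks.
#' @param kernel Conv kernel width.
#' @param pool Max-pool factor per sORFPred conv block.
#' @param d_model Transformer model dimension.
#' @param heads Attention heads.
#' @param n_transformer Transformer encoder layers.
#' @param stem_channels Per-modality stem channels (sORFPredRibo).
#' @param n_residual Residual conv blocks (sORFPredRibo).
#' @param upsample Down/up-sampling factor of the sORFPredRibo trunk and
#'   coverage decoder (3 = one token per codon).
#' @param window_nt sORFPredRibo input window, nt (pad/truncate).
#' @param lambda Weight of the coverage-regression loss.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param neg_ratio Negatives per positive in ORF example construction.
#' @param cov_min Mean per-base coverage above which a window counts as
#'   translated.
#' @param split Train/validation/test fractions (sum 1).
#' @param rng_seed Seed for init, shuffling and batching.
#' @return A `ModelConfig` list.
#' @export
model_config <- function(conv_channels = c(64L, 64L), kernel = 7L, pool = 2L,
                         d_model = 64L, heads = 4L, n_transformer = 2L,
                         stem_channels = 16L, n_residual = 2L, upsample = 3L,
                         window_nt = 303L, lambda = 1.0, lr = 1e-3,
                         batch_size = 64L, epochs = 15L, neg_ratio = 2,
                         cov_min = 0, split = c(0.8, 0.1, 0.1),
                         rng_seed = 1L) {
  stopifnot(abs(sum(split) - 1) < 1e-8, neg_ratio > 0, lambda >= 0,
            d_model %% heads == 0L, window_nt %% upsample == 0L)
  structure(list(conv_channels = as.integer(conv_channels),
                 kernel = as.integer(kernel), pool = as.integer(pool),
                 d_model = as.integer(d_model), heads = as.integer(heads),
                 n_transformer = as.integer(n_transformer),
                 stem_channels = as.integer(stem_channels),
                 n_residual = as.integer(n_residual),
                 upsample = as.integer(upsample),
                 window_nt = as.integer(window_nt), lambda = lambda, lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), neg_ratio = neg_ratio,
                 cov_min = cov_min, split = split,
                 rng_seed = as.integer(rng_seed)),
            class = "ModelConfig")
}

#' One-hot encode a DNA sequence
#'
#' Rows A, C, G, T; each column sums to 1 for those bases and is all-zero
#' for N.
#'
#' @param sequence DNA string over A/C/G/T/N.
#' @return 4 x L binary matrix with rownames A/C/G/T.
#' @export
one_hot <- function(sequence) {
  ch <- strsplit(toupper(sequence), "")[[1L]]
  m <- matrix(0, 4L, length(ch), dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(ch, rownames(m))
  ok <- !is.na(idx)
  m[cbind(idx[ok], which(ok))] <- 1
  m
}

# (N, L, 4) batch encoding of equal-length sequences.
encode_seq_batch <- function(seqs) {
  L <- nchar(seqs[1L])
  x <- array(0, c(length(seqs), L, 4L))
  for (i in seq_along(seqs)) x[i, , ] <- t(one_hot(seqs[i]))
  x
}

#' Scaled dot-product attention
#'
#' `softmax(Q K^T / sqrt(d_k)) V` with the softmax taken row-wise; each
#' output row is a convex combination of the rows of V.
#'
#' @param Q,K,V Query, key and value matrices; Q and K share `d_k` columns;
#'   K and V share row counts.
#' @param d_k Key dimension (defaults to `ncol(K)`).
#' @return The attention output matrix.
#' @export
attention <- function(Q, K, V, d_k = ncol(K)) {
  if (d_k == 0L) stop("d_k must be positive")
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  S <- tcrossprod(Q, K) / sqrt(d_k)
  S <- S - apply(S, 1L, max)
  W <- exp(S); W <- W / rowSums(W)
  W %*% V
}

TIS_UP <- 50L; TIS_DOWN <- 20L; TIS_LEN <- TIS_UP + 3L + TIS_DOWN  # 73 nt

# Fragment spanning 50 nt upstream of the codon through 20 nt downstream of
# its last base, in transcript orientation; NULL when flanks are truncated.
tis_fragment <- function(g, pos, strand) {
  slen <- nchar(g$sequence)
  if (strand == "+") {
    a <- pos - TIS_UP; b <- pos + 3L + TIS_DOWN
    if (a < 0L || b > slen) return(NULL)
    substr(g$sequence, a + 1L, b)
  } else {
    a <- pos - 2L - TIS_DOWN; b <- pos + 1L + TIS_UP
    if (a < 0L || b > slen) return(NULL)
    revcomp(substr(g$sequence, a + 1L, b))
  }
}

# 0-based genomic position of the first transcript base of the start codon.
cds_start_pos <- function(cds_row) {
  if (cds_row$strand == "+") cds_row$start else cds_row$end - 1L
}

assign_splits <- function(n, split, seed) {
  with_seed(seed, {
    ord <- sample.int(n)
    n_tr <- floor(split[1L] * n); n_va <- floor(split[2L] * n)
    s <- character(n)
    s[ord[seq_len(n_tr)]] <- "train"
    s[ord[n_tr + seq_len(n_va)]] <- "val"
    s[s == ""] <- "test"
    s
  })
}

#' Extract TIS training fragments
#'
#' Positives: annotated CDS starts with codon ATG/GTG/TTG and full 50/20
#' flanks. Negatives: genome-wide CTG occurrences (both strands) with full
#' flanks, optionally capped. Examples are shuffled and assigned to
#' train/val/test splits.
#'
#' @param genome A `GenomeSeq` or named list of them.
#' @param features Feature data.table.
#' @param config A [model_config()] (split fractions and seed).
#' @param neg_cap Optional maximum number of negatives (sampled with the
#'   config seed).
#' @return data.table: `fragment` (73 nt), `label`, `seqid`, `pos`,
#'   `strand`, `codon`, `split`.
#' @export
extract_tis_fragments <- function(genome, features, config = model_config(),
                                  neg_cap = NULL) {
  if (inherits(genome, "GenomeSeq"))
    genome <- stats::setNames(list(genome), genome$seqid)
  if (any(vapply(genome, function(g) nchar(g$sequence), integer(1L)) < TIS_LEN))
    stop("genome shorter than ", TIS_LEN, " nt")
  cds <- features[features$ftype == "CDS", ]
  rows <- list()
  for (i in seq_len(nrow(cds))) {
    row <- cds[i, ]
    g <- genome[[row$seqid]]
    pos <- cds_start_pos(row)
    codon <- if (row$strand == "+") substr(g$sequence, row$start + 1L, row$start + 3L)
             else revcomp(substr(g$sequence, row$end - 2L, row$end))
    if (!codon %in% START_CODONS) next
    frag <- tis_fragment(g, pos, row$strand)
    if (is.null(frag)) next                         # incomplete flank
    rows[[length(rows) + 1L]] <- data.table::data.table(
      fragment = frag, label = 1L, seqid = row$seqid, pos = pos,
      strand = row$strand, codon = codon)
  }
  for (g in genome) {
    for (std in c("+", "-")) {
      seq <- if (std == "+") g$sequence else revcomp(g$sequence)
      hits <- gregexpr("CTG", seq, fixed = TRUE)[[1L]]
      if (hits[1L] == -1L) next
      slen <- nchar(g$sequence)
      for (h in hits) {
        pos <- if (std == "+") h - 1L else slen - h   # first transcript base
        frag <- tis_fragment(g, pos, std)
        if (is.null(frag)) next
        rows[[length(rows) + 1L]] <- data.table::data.table(
          fragment = frag, label = 0L, seqid = g$seqid, pos = pos,
          strand = std, codon = "CTG")
      }
    }
  }
  ex <- data.table::rbindlist(rows)
  if (!is.null(neg_cap)) {
    neg <- which(ex$label == 0L)
    if (length(neg) > neg_cap) {
      drop <- with_seed(config$rng_seed,
                        sample(neg, length(neg) - neg_cap))
      ex <- ex[-drop, ]
    }
  }
  ex[, split := assign_splits(.N, config$split, config$rng_seed)]
  ex[]
}

#' Per-strand A-site coverage along the genome
#'
#' @param reads Read data.table.
#' @param genome A `GenomeSeq`.
#' @param rule A [offset_rule()].
#' @return List with numeric vectors `plus` and `minus` of genome length.
#' @export
asite_coverage <- function(reads, genome, rule = offset_rule()) {
  slen <- nchar(genome$sequence)
  plus <- numeric(slen); minus <- numeric(slen)
  if (nrow(reads) > 0L) {
    pos <- assign_asite(reads, rule)
    ok <- pos >= 0L & pos < slen
    pp <- pos[ok & reads$strand == "+"]
    mm <- pos[ok & reads$strand == "-"]
    if (length(pp)) plus <- tabulate(pp + 1L, nbins = slen)
    if (length(mm)) minus <- tabulate(mm + 1L, nbins = slen)
  }
  list(plus = as.numeric(plus), minus = as.numeric(minus))
}

window_seq_cov <- function(genome, cov, start, end, strand, window_nt) {
  seq <- substr(genome$sequence, start + 1L, end)
  v <- if (strand == "+") cov$plus[(start + 1L):end]
       else rev(cov$minus[(start + 1L):end])
  if (strand == "-") seq <- revcomp(seq)
  n <- nchar(seq)
  if (n >= window_nt) {
    seq <- substr(seq, 1L, window_nt); v <- v[seq_len(window_nt)]
  } else {
    seq <- paste0(seq, strrep("N", window_nt - n))
    v <- c(v, numeric(window_nt - n))
  }
  list(seq = seq, cov = v, raw_mean = mean(v[seq_len(min(n, window_nt))]))
}

#' Build sORFPredRibo training examples
#'
#' Positives are annotated CDS windows whose mean per-base A-site coverage
#' exceeds `cov_min`. Negatives are (a) reverse complements of positive
#' windows (carrying the opposite strand's coverage) and (b) the same
#' genomic windows shifted by +1 and +2 nt (frame-shift mutations), sampled
#' to `neg_ratio` negatives per positive. Coverage targets are per-position
#' density normalized to the window mean (zero where the window has no
#' reads).
#'
#' @param genome A `GenomeSeq`.
#' @param features Feature data.table.
#' @param reads Read data.table.
#' @param rule A [offset_rule()].
#' @param config A [model_config()].
#' @return data.table: `id`, `sequence`, `class_label`, `neg_kind`, `split`
#'   and a `coverage` list-column of normalized length-`window_nt` vectors.
#' @export
build_orf_examples <- function(genome, features, reads,
                               rule = offset_rule(), config = model_config()) {
  cov <- asite_coverage(reads, genome, rule)
  cds <- features[features$ftype == "CDS", ]
  W <- config$window_nt
  slen <- nchar(genome$sequence)
  norm_cov <- function(v) if (mean(v) > 0) v / mean(v) else v
  pos_rows <- list(); neg_rows <- list()
  for (i in seq_len(nrow(cds))) {
    row <- cds[i, ]
    w <- window_seq_cov(genome, cov, row$start, row$end, row$strand, W)
    if (w$raw_mean <= config$cov_min) next          # absence of coverage
    pos_rows[[length(pos_rows) + 1L]] <- data.table::data.table(
      id = paste0(row$gene_id, "_pos"), sequence = w$seq, class_label = 1L,
      neg_kind = "", coverage = list(norm_cov(w$cov)))
    # (a) reverse complement with the opposite strand's coverage
    anti <- if (row$strand == "+") "-" else "+"
    wa <- window_seq_cov(genome, cov, row$start, row$end, anti, W)
    neg_rows[[length(neg_rows) + 1L]] <- data.table::data.table(
      id = paste0(row$gene_id, "_rc"), sequence = wa$seq, class_label = 0L,
      neg_kind = "revcomp", coverage = list(norm_cov(wa$cov)))
    # (b) +1 / +2 frame-shifted windows
    for (sh in 1:2) {
      s2 <- row$start + sh; e2 <- min(row$end + sh, slen)
      ws <- window_seq_cov(genome, cov, s2, e2, row$strand, W)
      neg_rows[[length(neg_rows) + 1L]] <- data.table::data.table(
        id = paste0(row$gene_id, "_fs", sh), sequence = ws$seq,
        class_label = 0L, neg_kind = paste0("frameshift", sh),
        coverage = list(norm_cov(ws$cov)))
    }
  }
  if (!length(pos_rows)) stop("no positive window passes the coverage threshold")
  pos <- data.table::rbindlist(pos_rows)
  neg <- data.table::rbindlist(neg_rows)
  n_neg <- min(nrow(neg), round(config$neg_ratio * nrow(pos)))
  neg <- neg[with_seed(config$rng_seed, sample.int(nrow(neg), n_neg)), ]
  ex <- rbind(pos, neg)
  ex[, split := assign_splits(.N, config$split, config$rng_seed + 1L)]
  ex[]
}

# ---- network builders ------------------------------------------------------

build_sorfpred_net <- function(config) {
  ch <- config$conv_channels
  layers <- list(nn_conv1d(4L, ch[1L], config$kernel), nn_relu(),
                 nn_maxpool(config$pool),
                 nn_conv1d(ch[1L], ch[2L], config$kernel), nn_relu(),
                 nn_maxpool(config$pool))
  if (ch[2L] != config$d_model)
    layers <- c(layers, list(nn_conv1d(ch[2L], config$d_model, 1L)))
  layers <- c(layers, list(nn_posenc()))
  for (i in seq_len(config$n_transformer))
    layers <- c(layers, nn_transformer_block(config$d_model, config$heads))
  layers <- c(layers, list(nn_layernorm(config$d_model), nn_meanpool(),
                           nn_dense(config$d_model, 1L)))
  layers
}

# Returns list(stem_seq, stem_cov, trunk, head_class, head_cov).
build_sorfpredribo_net <- function(config) {
  sc <- config$stem_channels; D <- config$d_model
  stem_seq <- list(nn_conv1d(4L, sc, config$kernel), nn_relu())
  stem_cov <- list(nn_conv1d(1L, sc, config$kernel), nn_relu())
  trunk <- list()
  for (i in seq_len(config$n_residual))
    trunk <- c(trunk, list(nn_residual(list(
      nn_conv1d(2L * sc, 2L * sc, 5L), nn_relu(),
      nn_conv1d(2L * sc, 2L * sc, 5L))), nn_relu()))
  trunk <- c(trunk, list(nn_maxpool(config$upsample)))
  if (2L * sc != D) trunk <- c(trunk, list(nn_conv1d(2L * sc, D, 1L)))
  trunk <- c(trunk, list(nn_posenc()))
  for (i in seq_len(config$n_transformer))
    trunk <- c(trunk, nn_transformer_block(D, config$heads))
  trunk <- c(trunk, list(nn_layernorm(D)))
  head_class <- list(nn_meanpool(), nn_dense(D, 1L))
  # sub-pixel upsampling: one channel per intra-token offset, so the
  # decoder can express sub-codon phase directly
  head_cov <- list(nn_conv1d(D, D, 5L), nn_relu(),
                   nn_conv1d(D, config$upsample, 1L),
                   nn_subpixel(config$upsample))
  list(stem_seq = stem_seq, stem_cov = stem_cov, trunk = trunk,
       head_class = head_class, head_cov = head_cov)
}

epoch_metrics <- function(labels, probs) {
  m <- eval_classification(labels, probs)
  c(accuracy = m$accuracy, precision = m$precision, recall = m$recall,
    f1 = m$f1, roc_auc = m$roc_auc)
}

#' Train the sORFPred TIS classifier
#'
#' @param examples Output of [extract_tis_fragments()].
#' @param config A [model_config()].
#' @param quiet Suppress per-epoch messages.
#' @return A `sorfpred_model`: list with `net`, `config` and `report`
#'   (per-epoch training loss and validation accuracy/precision/recall/
#'   F1/ROC-AUC).
#' @export
train_sorfpred <- function(examples, config = model_config(), quiet = TRUE) {
  tr <- examples[examples$split == "train", ]
  va <- examples[examples$split == "val", ]
  if (length(unique(tr$label)) < 2L) stop("training split has a single class")
  x_tr <- encode_seq_batch(tr$fragment); y_tr <- tr$label
  x_va <- encode_seq_batch(va$fragment); y_va <- va$label
  with_seed(config$rng_seed, {
    net <- build_sorfpred_net(config)
    state <- adam_init()
    report <- list()
    n <- length(y_tr)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        fw <- seq_forward(net, x_tr[b, , , drop = FALSE])
        ls <- bce_loss(fw$out[, 1L], y_tr[b])
        bw <- seq_backward(net, matrix(ls$dlogits, ncol = 1L), fw$caches)
        up <- adam_step(net, bw$grads, state, lr = config$lr)
        net <- up$layers; state <- up$state
        losses <- c(losses, ls$loss)
      }
      p_va <- sigmoid(seq_forward(net, x_va)$out[, 1L])
      met <- epoch_metrics(y_va, p_va)
      report[[ep]] <- c(epoch = ep, loss = mean(losses), met)
      if (!quiet) message(sprintf("epoch %d loss %.4f val auc %.3f",
                                  ep, mean(losses), met[["roc_auc"]]))
    }
    structure(list(net = net, config = config,
                   report = data.table::as.data.table(do.call(rbind, report))),
              class = "sorfpred_model")
  })
}

#' Score candidate TIS and derive sORF calls with sORFPred
#'
#' Every ATG/GTG/TTG occurrence with full flanks on both strands is scored;
#' an occurrence whose nearest in-frame stop yields an ORF shorter than
#' `sorf_max_nt` is called an sORF candidate. Duplicate fragments are
#' deduplicated.
#'
#' @param model A trained `sorfpred_model`.
#' @param genome A `GenomeSeq` or named list of them.
#' @param threshold Decision threshold on the TIS probability.
#' @param sorf_max_nt sORF length bound (strict).
#' @return data.table: `seqid`, `pos`, `strand`, `codon`, `probability`,
#'   `predicted_tis`, `orf_length_nt`, `is_sorf`.
#' @export
predict_sorfpred <- function(model, genome, threshold = 0.5,
                             sorf_max_nt = 300L) {
  if (inherits(genome, "GenomeSeq"))
    genome <- stats::setNames(list(genome), genome$seqid)
  if (any(vapply(genome, function(g) nchar(g$sequence), integer(1L)) < TIS_LEN))
    stop("sequence shorter than ", TIS_LEN, " nt")
  orfs <- enumerate_orfs(genome, starts = START_CODONS, min_len = 9L)
  rows <- list()
  for (g in genome) {
    for (std in c("+", "-")) {
      seq <- if (std == "+") g$sequence else revcomp(g$sequence)
      slen <- nchar(g$sequence)
      for (codon in START_CODONS) {
        hits <- gregexpr(codon, seq, fixed = TRUE)[[1L]]
        if (hits[1L] == -1L) next
        for (h in hits) {
          pos <- if (std == "+") h - 1L else slen - h
          frag <- tis_fragment(g, pos, std)
          if (is.null(frag)) next
          rows[[length(rows) + 1L]] <- data.table::data.table(
            fragment = frag, seqid = g$seqid, pos = pos, strand = std,
            codon = codon)
        }
      }
    }
  }
  cand <- unique(data.table::rbindlist(rows), by = "fragment")  # dedup
  probs <- numeric(nrow(cand))
  for (b in split(seq_len(nrow(cand)),
                  ceiling(seq_len(nrow(cand)) / 256L))) {
    x <- encode_seq_batch(cand$fragment[b])
    probs[b] <- sigmoid(seq_forward(model$net, x)$out[, 1L])
  }
  ostart <- ifelse(cand$strand == "+", cand$pos, NA_integer_)
  key_cand <- paste(cand$seqid, cand$strand,
                    ifelse(cand$strand == "+", cand$pos, cand$pos - 2L))
  key_orf <- paste(orfs$seqid, orfs$strand,
                   ifelse(orfs$strand == "+", orfs$start, orfs$end - 3L))
  olen <- orfs$length_nt[match(key_cand, key_orf)]
  out <- data.table::data.table(seqid = cand$seqid, pos = cand$pos,
                                strand = cand$strand, codon = cand$codon,
                                probability = probs,
                                predicted_tis = probs > threshold,
                                orf_length_nt = olen,
                                is_sorf = !is.na(olen) & olen < sorf_max_nt &
                                          probs > threshold)
  data.table::setorder(out, seqid, pos)
  out[]
}

ribo_forward <- function(net, xs, xc) {
  fs <- seq_forward(net$stem_seq, xs)
  fc <- seq_forward(net$stem_cov, xc)
  n <- dim(fs$out)[1L]; L <- dim(fs$out)[2L]
  cat_ <- array(0, c(n, L, dim(fs$out)[3L] + dim(fc$out)[3L]))
  cat_[, , seq_len(dim(fs$out)[3L])] <- fs$out
  cat_[, , dim(fs$out)[3L] + seq_len(dim(fc$out)[3L])] <- fc$out
  ft <- seq_forward(net$trunk, cat_)
  hc <- seq_forward(net$head_class, ft$out)
  hv <- seq_forward(net$head_cov, ft$out)
  list(logits = hc$out[, 1L], cov_pred = hv$out,
       caches = list(fs = fs$caches, fc = fc$caches, ft = ft$caches,
                     hc = hc$caches, hv = hv$caches),
       n_seq_ch = dim(fs$out)[3L])
}

ribo_backward <- function(net, fw, dlogits, dcov) {
  bc <- seq_backward(net$head_class, matrix(dlogits, ncol = 1L), fw$caches$hc)
  bv <- seq_backward(net$head_cov, dcov, fw$caches$hv)
  bt <- seq_backward(net$trunk, bc$dx + bv$dx, fw$caches$ft)
  ns <- fw$n_seq_ch
  d_seq <- bt$dx[, , seq_len(ns), drop = FALSE]
  d_cov <- bt$dx[, , (ns + 1L):dim(bt$dx)[3L], drop = FALSE]
  bs <- seq_backward(net$stem_seq, d_seq, fw$caches$fs)
  bcv <- seq_backward(net$stem_cov, d_cov, fw$caches$fc)
  list(stem_seq = bs$grads, stem_cov = bcv$grads, trunk = bt$grads,
       head_class = bc$grads, head_cov = bv$grads)
}

ribo_update <- function(net, grads, states, lr) {
  for (part in names(net)) {
    up <- adam_step(net[[part]], grads[[part]], states[[part]], lr = lr)
    net[[part]] <- up$layers
    states[[part]] <- up$state
  }
  list(net = net, states = states)
}

examples_to_arrays <- function(ex, W) {
  xs <- encode_seq_batch(ex$sequence)
  xc <- array(0, c(nrow(ex), W, 1L))
  for (i in seq_len(nrow(ex))) xc[i, , 1L] <- ex$coverage[[i]]
  list(xs = xs, xc = xc, y = ex$class_label)
}

#' Train the sORFPredRibo multimodal model
#'
#' Joint loss: binary cross-entropy on the classification head plus
#' `lambda` times the MSE of the coverage head against the normalized
#' coverage target. Pass a pretrained model as `init` to fine-tune
#' (pretraining is the same routine run on pooled multi-genome examples).
#'
#' @param examples Output of [build_orf_examples()] (or pooled rbind of
#'   several).
#' @param config A [model_config()].
#' @param init Optional `sorfpredribo_model` whose weights initialize
#'   training.
#' @param quiet Suppress per-epoch messages.
#' @return A `sorfpredribo_model`: `net`, `config`, `report` (per-epoch
#'   loss, classification metrics, coverage MSE/MAE/Pearson).
#' @export
train_sorfpredribo <- function(examples, config = model_config(),
                               init = NULL, quiet = TRUE) {
  W <- config$window_nt
  if (any(lengths(examples$coverage) != W))
    stop("coverage length differs from the configured window")
  tr <- examples[examples$split == "train", ]
  va <- examples[examples$split == "val", ]
  if (length(unique(tr$class_label)) < 2L) stop("training split has a single class")
  dtr <- examples_to_arrays(tr, W)
  dva <- examples_to_arrays(va, W)
  cov_tr <- array(0, c(nrow(tr), W, 1L))
  for (i in seq_len(nrow(tr))) cov_tr[i, , 1L] <- tr$coverage[[i]]
  with_seed(config$rng_seed, {
    net <- if (is.null(init)) build_sorfpredribo_net(config) else init$net
    states <- lapply(net, function(x) adam_init())
    report <- list()
    n <- nrow(tr)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        fw <- ribo_forward(net, dtr$xs[b, , , drop = FALSE],
                           dtr$xc[b, , , drop = FALSE])
        ls <- bce_loss(fw$logits, dtr$y[b])
        resid <- fw$cov_pred - cov_tr[b, , , drop = FALSE]
        mse <- mean(resid^2)
        dcov <- config$lambda * 2 * resid / length(resid)
        gr <- ribo_backward(net, fw, ls$dlogits, dcov)
        up <- ribo_update(net, gr, states, config$lr)
        net <- up$net; states <- up$states
        losses <- c(losses, ls$loss + config$lambda * mse)
      }
      fwv <- ribo_forward(net, dva$xs, dva$xc)
      p_va <- sigmoid(fwv$logits)
      met <- epoch_metrics(dva$y, p_va)
      cov_true <- vapply(va$coverage, identity, numeric(W))
      reg <- eval_regression(as.numeric(cov_true),
                             as.numeric(t(fwv$cov_pred[, , 1L])))
      report[[ep]] <- c(epoch = ep, loss = mean(losses), met,
                        cov_mse = reg$mse, cov_mae = reg$mae,
                        cov_pearson = reg$pearson_r)
      if (!quiet) message(sprintf("epoch %d loss %.4f val auc %.3f cov r %.3f",
                                  ep, mean(losses), met[["roc_auc"]],
                                  reg$pearson_r))
    }
    structure(list(net = net, config = config,
                   report = data.table::as.data.table(do.call(rbind, report))),
              class = "sorfpredribo_model")
  })
}

#' Score candidate windows with sORFPredRibo
#'
#' All candidates are scored; the sORF report is restricted to candidates
#' shorter than `sorf_max_nt` (strict), with an optional high-confidence
#' probability filter.
#'
#' @param model A trained `sorfpredribo_model`.
#' @param candidates data.table with `id`, `sequence`, a `coverage`
#'   list-column and `length_nt` (true candidate length before
#'   pad/truncate; defaults to `nchar(sequence)`).
#' @param high_conf Probability bound for the high-confidence subset
#'   (strict).
#' @param sorf_max_nt sORF length bound (strict).
#' @return List: `all` (id, probability, predicted coverage list-column),
#'   `sorf` (subset with `length_nt < sorf_max_nt`), `high_confidence`
#'   (sorf subset with `probability > high_conf`).
#' @export
predict_sorfpredribo <- function(model, candidates, high_conf = 0.99,
                                 sorf_max_nt = 300L) {
  W <- model$config$window_nt
  if (any(lengths(candidates$coverage) != W))
    stop("coverage length differs from the model window after pad/truncate")
  if (is.null(candidates$length_nt))
    candidates$length_nt <- nchar(candidates$sequence)
  d <- examples_to_arrays(
    data.table::data.table(sequence = candidates$sequence,
                           coverage = candidates$coverage,
                           class_label = 0L), W)
  fw <- ribo_forward(model$net, d$xs, d$xc)
  all_tab <- data.table::data.table(
    id = candidates$id, length_nt = candidates$length_nt,
    probability = sigmoid(fw$logits),
    cov_pred = lapply(seq_len(nrow(candidates)),
                      function(i) fw$cov_pred[i, , 1L]))
  sorf <- all_tab[all_tab$length_nt < sorf_max_nt, ]
  list(all = all_tab, sorf = sorf,
       high_confidence = sorf[sorf$probability > high_conf, ])
}

#' Classification metrics
#'
#' Accuracy, precision, recall and F1 at the threshold; ROC-AUC by
#' trapezoidal integration of the TPR/FPR curve over unique score cutoffs
#' (equivalently the pairwise-concordance probability, ties counting one
#' half); PR-AUC by trapezoidal integration of the precision/recall curve.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Real scores.
#' @param threshold Classification threshold.
#' @return List: `n`, `accuracy`, `precision`, `recall`, `f1`, `roc_auc`,
#'   `pr_auc`, `tpr`, `fpr`.
#' @export
eval_classification <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores))
  if (length(unique(labels)) < 2L)
    stop("ROC-AUC undefined for single-class labels")
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & labels == 1L); fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L); tn <- sum(pred == 0L & labels == 0L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- tp / (tp + fn)
  f1 <- if (is.na(precision) || precision + recall == 0) NA_real_
        else 2 * precision * recall / (precision + recall)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  grp <- cumsum(!duplicated(sc))
  ctp <- cumsum(lab); cfp <- cumsum(1 - lab)
  last <- !duplicated(grp, fromLast = TRUE)       # end of each tie group
  tpr <- c(0, ctp[last] / sum(labels))
  fpr <- c(0, cfp[last] / sum(1 - labels))
  roc_auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  prec_c <- ctp[last] / (ctp[last] + cfp[last])
  rec_c <- ctp[last] / sum(labels)
  rec_full <- c(0, rec_c)
  prec_full <- c(prec_c[1L], prec_c)
  pr_auc <- sum(diff(rec_full) *
                (utils::head(prec_full, -1) + utils::tail(prec_full, -1)) / 2)
  list(n = length(labels), accuracy = (tp + tn) / length(labels),
       precision = precision, recall = recall, f1 = f1,
       roc_auc = roc_auc, pr_auc = pr_auc, tpr = tpr, fpr = fpr)
}

#' Regression metrics
#'
#' `MSE = mean((y_true - y_pred)^2)`, `MAE = mean(|y_true - y_pred|)`, plus
#' the Pearson correlation (NA when either vector is constant).
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return List: `n`, `mse`, `mae`, `pearson_r`.
#' @export
eval_regression <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  stopifnot(length(y_true) == length(y_pred))
  r <- if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0) NA_real_
       else stats::cor(y_true, y_pred)
  list(n = length(y_true), mse = mean((y_true - y_pred)^2),
       mae = mean(abs(y_true - y_pred)), pearson_r = r)
}
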