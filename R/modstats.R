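# Two-group moderated linear-model testing shared by the differential
# translation-efficiency and codon-occupancy pipelines.
#
# Per feature g with pooled residual variance s_g^2 on d_g df, the
# empirical-Bayes posterior variance is
#   s_post^2 = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)
# and the moderated t is logFC / (s_post * sqrt(1/n1 + 1/n2)) on d0 + d_g
# df. (d0, s0^2) are estimated by moment-matching of the log sample
# variances against the scaled-F prior.

#' Newton inversion of the trigamma function
#'
#' Solves `trigamma(y) = x` for `y > 0`.
#'
#' @param x Positive target value(s).
#' @return `y` with `trigamma(y) = x`.
#' @keywords internal
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (iter in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif / y) < 1e-10) break
    }
    y
  }, numeric(1L))
}

# Method-of-moments fit of the scaled-F prior to sample variances s2 on df
# degrees of freedom; returns list(d0, s02).
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  s2 <- s2[ok]; df <- df[ok]
  if (length(s2) < 2L) return(list(d0 = 0, s02 = mean(s2)))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated two-group fit
#'
#' Ordinary least-squares two-group fit per feature with empirical-Bayes
#' variance shrinkage. `logFC` is group2 minus group1 of the (already
#' log-scale) values. `d0` may be forced: `0` recovers the classical
#' two-sample pooled-variance t-test, `Inf` the fully pooled prior-variance
#' limit.
#'
#' @param log_matrix Numeric matrix, features x samples, on the log2 scale.
#'   NA entries are allowed; features with fewer than one sample per group
#'   are masked.
#' @param groups Vector of 1/2 (or a two-level factor) over columns.
#' @param d0 Optional forced prior degrees of freedom.
#' @param var_floor Lower bound applied to residual variances before
#'   shrinkage, guarding exact ties.
#' @return A `ModeratedFitResult` data.table: `feature_id`, `logFC`,
#'   `t_mod`, `p_value`, `fdr`, `s2_post`, `df_total`; attributes
#'   `s2_prior`, `d0`.
#' @export
moderated_fit <- function(log_matrix, groups, d0 = NULL, var_floor = 1e-12) {
  if (is.factor(groups) || is.character(groups))
    groups <- as.integer(factor(groups))
  stopifnot(ncol(log_matrix) == length(groups), all(groups %in% 1:2))
  g1 <- which(groups == 1L); g2 <- which(groups == 2L)
  if (!length(g1) || !length(g2)) stop("both groups need at least one sample")

  n1 <- rowSums(!is.na(log_matrix[, g1, drop = FALSE]))
  n2 <- rowSums(!is.na(log_matrix[, g2, drop = FALSE]))
  m1 <- rowMeans(log_matrix[, g1, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(log_matrix[, g2, drop = FALSE], na.rm = TRUE)
  logfc <- m2 - m1

  dev1 <- sweep(log_matrix[, g1, drop = FALSE], 1L, m1)
  dev2 <- sweep(log_matrix[, g2, drop = FALSE], 1L, m2)
  rss <- rowSums(dev1^2, na.rm = TRUE) + rowSums(dev2^2, na.rm = TRUE)
  dg <- pmax(n1 + n2 - 2, 0)
  s2 <- ifelse(dg > 0, pmax(rss / dg, var_floor), NA_real_)

  prior <- if (is.null(d0)) fit_variance_prior(s2, dg)
           else list(d0 = d0, s02 = {
             p <- fit_variance_prior(s2, dg); p$s02
           })
  d0 <- prior$d0; s02 <- prior$s02
  if (!is.finite(s02) || s02 <= 0) s02 <- max(mean(s2, na.rm = TRUE), var_floor)

  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else ifelse(dg > 0, (d0 * s02 + dg * s2) / (d0 + dg),
                         if (d0 > 0) s02 else NA_real_)
  df_tot <- d0 + dg
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- logfc / se
  p <- ifelse(is.finite(df_tot),
              2 * stats::pt(abs(t_mod), df = df_tot, lower.tail = FALSE),
              2 * stats::pnorm(abs(t_mod), lower.tail = FALSE))
  usable <- n1 >= 1 & n2 >= 1 & is.finite(se) & se > 0 & df_tot > 0
  t_mod[!usable] <- NA_real_; p[!usable] <- NA_real_
  fid <- rownames(log_matrix)
  if (is.null(fid)) fid <- sprintf("f%05d", seq_len(nrow(log_matrix)))
  out <- data.table::data.table(feature_id = fid, logFC = logfc, t_mod = t_mod,
                                p_value = p,
                                fdr = stats::p.adjust(p, method = "BH"),
                                s2_post = s2_post, df_total = df_tot)
  data.table::setattr(out, "s2_prior", s02)
  data.table::setattr(out, "d0", d0)
  out[]
}

#' Classify features from a moderated fit
#'
#' `up` if `logFC >= lfc_thresh` and `p < p_thresh`; `down` if
#' `logFC <= -lfc_thresh` and `p < p_thresh`; otherwise `ns`. The fold-change
#' bound is inclusive, the p-value bound strict. Classification uses
#' unadjusted p-values; the BH-adjusted column is carried along for callers
#' who prefer it.
#'
#' @param result A [moderated_fit()] result.
#' @param lfc_thresh Absolute log2 fold-change threshold.
#' @param p_thresh P-value threshold.
#' @return The result with a `status` column (`up`/`down`/`ns`).
#' @export
classify_hits <- function(result, lfc_thresh = 1.5, p_thresh = 0.05) {
  out <- data.table::copy(result)
  out[, status := "ns"]
  out[!is.na(p_value) & p_value < p_thresh & logFC >= lfc_thresh, status := "up"]
  out[!is.na(p_value) & p_value < p_thresh & logFC <= -lfc_thresh, status := "down"]
  out[]
}
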