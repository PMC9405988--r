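# Significant connectivity against baseline: two-sample t-statistics per
# channel pair with family-wise error control by the single-threshold
# max-statistic permutation method. Condition labels are exchanged within
# subject (each subject contributes both event and baseline epochs, with
# possibly unequal counts), honouring the related-sample structure.

#' Pooled-variance two-sample t-statistic
#'
#' The per-pair statistic of the permutation test. A t-statistic is used
#' instead of the raw mean difference so that high-variance pairs do not
#' dominate the maximum statistic: dividing by the standard error makes
#' the null sampling distribution comparable across pairs, which the
#' single-threshold method assumes.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return t = (mean(a) - mean(b)) / SE with the pooled-variance SE.
#' @export
pair_tstat <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("both samples need at least 2 observations")
  }
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  if (sp2 <= 0) stop("zero pooled variance: degenerate sample")
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

#' Rank of the critical value in the permutation-maximum distribution
#'
#' The single-threshold critical value is the (c+1)th largest member of
#' the distribution of permutation maxima, with c = floor(alpha * N).
#'
#' @param alpha Significance level in (0, 1).
#' @param n_perm Number of permutations N.
#' @return Integer rank c + 1 (1 = the maximum itself).
#' @export
critical_index <- function(alpha, n_perm) {
  stopifnot(alpha > 0, alpha < 1, n_perm >= 1)
  as.integer(floor(alpha * n_perm) + 1)
}

#' Max-statistic permutation test of event vs baseline connectivity
#'
#' For each channel pair the observed |t| (event PLVs vs baseline PLVs,
#' pooled variance) is compared against the permutation distribution of
#' the MAXIMUM |t| over all pairs, obtained by re-randomizing the
#' event/baseline condition labels within each subject (keeping each
#' subject's condition counts). This single-threshold procedure controls
#' the family-wise error rate across all pairs simultaneously. The test
#' is two-sided: both hyper- and hypo-synchrony relative to baseline can
#' be detected.
#'
#' Adjusted p-values use the add-one convention,
#' `p = (1 + #\{max_k >= |t_obs|\}) / (n_perm + 1)`, so the smallest
#' attainable p is `1 / (n_perm + 1)`.
#'
#' @param plv_group Events x pairs matrix of PLVs for the condition of
#'   interest.
#' @param plv_baseline Baseline-epochs x pairs matrix.
#' @param subjects_group,subjects_baseline Subject label per row of the
#'   respective matrix; every subject must appear in both conditions.
#' @param alpha Family-wise level (default 0.01).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `significance_result`: `t_obs` (signed t per
#'   pair), `null_max`, `critical_value` (the (c+1)th largest maximum,
#'   c = floor(alpha * n_perm)), `p_adj`, `mask`, plus the call
#'   parameters.
#' @export
max_stat_test <- function(plv_group, plv_baseline,
                          subjects_group, subjects_baseline,
                          alpha = 0.01, n_perm = 1000, seed = 1L) {
  plv_group <- as.matrix(plv_group)
  plv_baseline <- as.matrix(plv_baseline)
  if (ncol(plv_group) != ncol(plv_baseline)) {
    stop("condition matrices disagree on the number of pairs")
  }
  if (nrow(plv_group) < 2 || nrow(plv_baseline) < 2) {
    stop("each condition needs at least 2 observations")
  }
  stopifnot(length(subjects_group) == nrow(plv_group),
            length(subjects_baseline) == nrow(plv_baseline))
  subs <- union(subjects_group, subjects_baseline)
  only_one <- subs[!(subs %in% subjects_group & subs %in% subjects_baseline)]
  if (length(only_one)) {
    stop("subject(s) present in only one condition: ",
         paste(only_one, collapse = ", "),
         "; within-subject label exchange requires both")
  }
  X <- rbind(plv_group, plv_baseline)
  subj <- c(as.character(subjects_group), as.character(subjects_baseline))
  is_a_obs <- c(rep(TRUE, nrow(plv_group)), rep(FALSE, nrow(plv_baseline)))

  na <- nrow(plv_group); nb <- nrow(plv_baseline)
  ma <- colMeans(plv_group); mb <- colMeans(plv_baseline)
  va <- apply(plv_group, 2, stats::var)
  vb <- apply(plv_baseline, 2, stats::var)
  sp2 <- pmax(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2),
              .Machine$double.eps)
  t_obs <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))

  by_subj <- split(seq_along(subj), subj)
  n_a_subj <- vapply(by_subj, function(ix) sum(is_a_obs[ix]), integer(1))
  n_tot <- nrow(X)
  # indicator matrix of condition-A membership per permutation, then all
  # per-pair statistics at once via two crossproducts
  IA <- with_seed(seed, {
    M <- matrix(0, n_perm, n_tot)
    for (k in seq_len(n_perm)) {
      for (si in seq_along(by_subj)) {
        M[k, sample(by_subj[[si]], n_a_subj[si])] <- 1
      }
    }
    M
  })
  X2 <- X^2
  cs <- colSums(X); cs2 <- colSums(X2)
  SA <- IA %*% X;  SA2 <- IA %*% X2
  SB <- matrix(cs, n_perm, ncol(X), byrow = TRUE) - SA
  SB2 <- matrix(cs2, n_perm, ncol(X), byrow = TRUE) - SA2
  MA <- SA / na; MB <- SB / nb
  VA <- (SA2 - na * MA^2) / (na - 1)
  VB <- (SB2 - nb * MB^2) / (nb - 1)
  SP2 <- pmax(((na - 1) * VA + (nb - 1) * VB) / (na + nb - 2),
              .Machine$double.eps)
  Tmat <- abs(MA - MB) / sqrt(SP2 * (1 / na + 1 / nb))
  null_max <- apply(Tmat, 1, max)
  p_adj <- vapply(abs(t_obs), function(t0)
    (1 + sum(null_max >= t0)) / (n_perm + 1), numeric(1))
  crit <- sort(null_max, decreasing = TRUE)[critical_index(alpha, n_perm)]
  structure(list(
    t_obs = t_obs, null_max = null_max, critical_value = crit,
    p_adj = p_adj, mask = p_adj < alpha,
    alpha = alpha, n_perm = n_perm, seed = seed,
    n_group = na, n_baseline = nb
  ), class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf(
    "<significance_result> %d pairs, %d significant at alpha = %g (n_perm = %d, crit |t| = %.3f)\n",
    length(x$t_obs), sum(x$mask), x$alpha, x$n_perm, x$critical_value))
  invisible(x)
}

#' Write a significance result as an edge-list TSV
#'
#' @param sig A `significance_result`.
#' @param pairs The [pair_index()] frame the statistics are aligned to.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_significance_tsv <- function(sig, pairs, path) {
  stopifnot(nrow(pairs) == length(sig$t_obs))
  out <- data.frame(channel_a = pairs$chan_a, channel_b = pairs$chan_b,
                    t = sig$t_obs, p_adj = sig$p_adj,
                    significant = sig$mask)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
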