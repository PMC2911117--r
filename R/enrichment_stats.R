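#' Maximum-likelihood fold-enrichment estimate
#'
#' Fold enrichment of a repeat set under a Poisson model with a
#' non-informative half-count prior:
#' \deqn{\hat\theta = \frac{C (s + 1/2)}{S (c + 1/2)}}
#' where `s` and `c` are the ChIP (signal) and control reads uniquely
#' associated with the set, and `S` and `C` are the effective dataset sizes.
#' The half-count regularization keeps the estimate finite and positive at
#' zero counts.
#'
#' @param s,c Signal and control read counts (non-negative, vectorized).
#' @param S,C Signal and control dataset sizes (positive).
#' @return The fold-enrichment MLE(s).
#' @export
enrichment_mle <- function(s, c, S, C) {
  if (any(S <= 0) || any(C <= 0)) stop("dataset sizes S and C must be positive")
  if (any(s < 0) || any(c < 0)) stop("counts must be non-negative")
  C * (s + 0.5) / (S * (c + 0.5))
}

#' Confidence interval for the fold enrichment
#'
#' Interval bounds are quantiles of the posterior of the enrichment ratio,
#' \eqn{\lambda(x) = \hat\theta \, F[x;\, 2(s+1/2),\, 2(c+1/2)]} with `F` the
#' F-distribution quantile function; both `alpha/2` and `1 - alpha/2` values
#' are computed and sorted, which makes the result independent of the tail
#' convention.
#'
#' @inheritParams enrichment_mle
#' @param alpha Significance level (default 0.05 for a 95\% CI).
#' @return A two-column matrix (or length-2 vector for scalar input) with
#'   `ci_low` and `ci_high`.
#' @export
enrichment_ci <- function(s, c, S, C, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  mle <- enrichment_mle(s, c, S, C)
  df1 <- 2 * (s + 0.5)
  df2 <- 2 * (c + 0.5)
  a <- mle * stats::qf(alpha / 2, df1, df2)
  b <- mle * stats::qf(1 - alpha / 2, df1, df2)
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  if (length(mle) == 1L) return(c(ci_low = lo, ci_high = hi))
  cbind(ci_low = lo, ci_high = hi)
}

#' Signed, capped enrichment Z-score
#'
#' Significance of enrichment or depletion expressed on the normal-quantile
#' scale: a two-sided exact binomial test of `s` signal reads among `s + c`
#' set reads against the null proportion `S / (S + C)` is converted to
#' \eqn{Z = \mathrm{sign}(\hat\theta - 1)\,\Phi^{-1}(1 - p/2)}, so a Z-score
#' of 3.1 corresponds to a one-sided P-value of 1e-3. The magnitude is
#' capped (default at 10).
#'
#' @inheritParams enrichment_mle
#' @param cap Maximum |Z| reported (default 10).
#' @return Signed Z-score(s) with `|Z| <= cap`.
#' @export
enrichment_zscore <- function(s, c, S, C, cap = 10) {
  n <- max(length(s), length(c), length(S), length(C))
  s <- rep_len(s, n); c <- rep_len(c, n)
  S <- rep_len(S, n); C <- rep_len(C, n)
  mle <- enrichment_mle(s, c, S, C)
  z <- numeric(n)
  for (i in seq_len(n)) {
    tot <- s[i] + c[i]
    if (tot == 0) { z[i] <- 0; next }
    p0 <- S[i] / (S[i] + C[i])
    pv <- stats::binom.test(s[i], tot, p = p0)$p.value
    q <- stats::qnorm(pv / 2, lower.tail = FALSE)
    z[i] <- sign(mle[i] - 1) * min(q, cap)
  }
  z
}

#' Full enrichment estimate table for one mark
#'
#' Convenience wrapper combining [enrichment_mle()], [enrichment_ci()] and
#' [enrichment_zscore()]. A set is significant when its CI excludes 1.
#'
#' @param set_id Identifiers of the repeat sets (types or tree nodes).
#' @inheritParams enrichment_mle
#' @param alpha Significance level (default 0.05).
#' @param cap Z-score cap (default 10).
#' @return A `data.frame(set_id, s, c, S, C, mle, ci_low, ci_high, zscore,
#'   significant)`.
#' @export
estimate_enrichment <- function(set_id, s, c, S, C, alpha = 0.05, cap = 10) {
  mle <- enrichment_mle(s, c, S, C)
  ci <- enrichment_ci(s, c, S, C, alpha = alpha)
  if (is.null(dim(ci))) ci <- matrix(ci, nrow = 1,
                                     dimnames = list(NULL, c("ci_low", "ci_high")))
  z <- enrichment_zscore(s, c, S, C, cap = cap)
  data.frame(set_id = set_id, s = s, c = c, S = S, C = C, mle = mle,
             ci_low = ci[, "ci_low"], ci_high = ci[, "ci_high"], zscore = z,
             significant = ci[, "ci_low"] > 1 | ci[, "ci_high"] < 1,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare two enrichment estimates as a ratio of binomial proportions
#'
#' Tests whether two fold-enrichment coefficients (for instance the
#' canonical-only and instance-only estimates of the same repeat type) are
#' consistent, via an approximate Bayesian confidence interval for their
#' ratio in the style of Price and Bonett: each of the four proportions gets
#' a +1/2 count adjustment, and the log-ratio variance is the sum of
#' `1/(x + 1/2) - 1/(n + 1/2)` terms.
#'
#' @param s1,c1,S1,C1 Counts and dataset sizes of the first estimate.
#' @param s2,c2,S2,C2 Counts and dataset sizes of the second estimate.
#' @param alpha Significance level (default 0.05).
#' @return A list with `ratio` (point estimate of \eqn{\theta_1/\theta_2}),
#'   `ci_low`, `ci_high`, and `consistent` (`TRUE` when the CI contains 1).
#' @export
compare_estimates <- function(s1, c1, S1, C1, s2, c2, S2, C2, alpha = 0.05) {
  if (any(c(S1, C1, S2, C2) <= 0)) stop("dataset sizes must be positive")
  lt1 <- log((s1 + 0.5) / (S1 + 0.5)) - log((c1 + 0.5) / (C1 + 0.5))
  lt2 <- log((s2 + 0.5) / (S2 + 0.5)) - log((c2 + 0.5) / (C2 + 0.5))
  v1 <- 1 / (s1 + 0.5) - 1 / (S1 + 0.5) + 1 / (c1 + 0.5) - 1 / (C1 + 0.5)
  v2 <- 1 / (s2 + 0.5) - 1 / (S2 + 0.5) + 1 / (c2 + 0.5) - 1 / (C2 + 0.5)
  lr <- lt1 - lt2
  hw <- stats::qnorm(1 - alpha / 2) * sqrt(v1 + v2)
  ci <- exp(c(lr - hw, lr + hw))
  list(ratio = exp(lr), ci_low = ci[1], ci_high = ci[2],
       consistent = ci[1] <= 1 && 1 <= ci[2])
}

#' Cluster repeat types by their enrichment profile across marks
#'
#' Rows (repeat types) are clustered with Ward's method on the Euclidean
#' distance of transformed enrichment profiles: cells that are not
#' statistically significant are set to 0, and significant depletion
#' (MLE < 1) is also set to 0 for clustering (it is retained for display).
#' The profile scale is log2(MLE), so depletion corresponds to negative
#' values, zeroed per the transformation.
#'
#' @param mle_matrix Numeric matrix of MLEs, repeat types in rows, marks in
#'   columns, with rownames and colnames.
#' @param significant Logical matrix of the same shape flagging cells whose
#'   CI excludes 1.
#' @return A list with `order` (row ordering), `hclust` (the dendrogram),
#'   `values` (the transformed matrix used for clustering) and `display`
#'   (log2 MLE with non-significant cells zeroed but depletion retained).
#' @export
cluster_types <- function(mle_matrix, significant) {
  stopifnot(is.matrix(mle_matrix), all(dim(mle_matrix) == dim(significant)))
  if (nrow(mle_matrix) < 2L) stop("need at least two repeat types to cluster")
  lm <- log2(mle_matrix)
  display <- ifelse(significant, lm, 0)
  values <- ifelse(significant & lm > 0, lm, 0)
  if (all(values == 0)) {
    warning("no significant enrichment anywhere; clustering is trivial")
  }
  hc <- stats::hclust(stats::dist(values), method = "ward.D2")
  list(order = hc$order, hclust = hc, values = values, display = display)
}

#' Hypergeometric family over-representation within a cluster
#'
#' Upper-tail hypergeometric test of whether a repeat family is
#' over-represented among the members of a cluster, with multiple-testing
#' correction across the families tested (Bonferroni by default, the
#' conservative reading of a "corrected" P-value).
#'
#' @param cluster_members Character vector of repeat types in the cluster.
#' @param universe Character vector of all repeat types considered.
#' @param family_labels Named character vector mapping each type in
#'   `universe` to its family.
#' @param method Multiple-testing correction passed to [stats::p.adjust()]
#'   (default `"bonferroni"`).
#' @return A `data.frame(family, n_cluster, n_universe, p_raw, p_corrected)`
#'   sorted by corrected P-value.
#' @export
family_overrepresentation <- function(cluster_members, universe, family_labels,
                                      method = "bonferroni") {
  if (length(cluster_members) == 0L) stop("cluster is empty")
  if (!all(cluster_members %in% universe)) {
    stop("cluster members must be a subset of the universe")
  }
  fam <- family_labels[universe]
  if (anyNA(fam)) stop("family_labels must cover every type in the universe")
  families <- sort(unique(fam))
  N <- length(universe)
  n <- length(cluster_members)
  cl_fam <- family_labels[cluster_members]
  res <- lapply(families, function(f) {
    m <- sum(fam == f)
    k <- sum(cl_fam == f)
    p <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    data.frame(family = f, n_cluster = k, n_universe = m, p_raw = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_corrected <- stats::p.adjust(res$p_raw, method = method)
  res[order(res$p_corrected, res$p_raw), , drop = FALSE]
}
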