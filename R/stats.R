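#' Two-proportion comparisons for read counts
#'
#' Single amplicon libraries are compared as proportions of reads: k guild
#' (or genus) reads out of n total reads per sample. The exact two-sided
#' p-value comes from the conditional (hypergeometric) distribution of the
#' 2x2 table — Fisher's exact test, the permutation view of a difference in
#' proportions — and the confidence interval for the difference p1 - p2 from
#' the Newcombe hybrid score method built on per-sample Wilson intervals.
#'
#' @name two-proportion
NULL

#' Wilson score interval for a binomial proportion
#'
#' Inverts the score test: center (p + z^2/2n)/(1 + z^2/n), half-width
#' z*sqrt(p(1-p)/n + z^2/4n^2)/(1 + z^2/n), bounds clipped to \[0, 1\].
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param conf confidence level.
#' @return numeric vector `c(low, high)`.
#' @export
wilson_interval <- function(k, n, conf = 0.95) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (k < 0 || k > n) stop("k must lie in [0, n]", call. = FALSE)
  z <- stats::qnorm((1 + conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, center - half), high = min(1, center + half))
}

#' Newcombe hybrid score interval for a difference of proportions
#'
#' With per-sample Wilson intervals (l1,u1), (l2,u2) and d = p1 - p2:
#' low = d - sqrt((p1-l1)^2 + (u2-p2)^2),
#' high = d + sqrt((u1-p1)^2 + (p2-l2)^2), clipped to \[-1, 1\].
#'
#' @param k1,n1 successes and trials in the first sample.
#' @param k2,n2 successes and trials in the second sample.
#' @param conf confidence level.
#' @return numeric vector `c(low, high)`.
#' @export
newcombe_diff_interval <- function(k1, n1, k2, n2, conf = 0.95) {
  w1 <- wilson_interval(k1, n1, conf)
  w2 <- wilson_interval(k2, n2, conf)
  p1 <- k1 / n1; p2 <- k2 / n2
  d <- p1 - p2
  c(low = max(-1, d - sqrt((p1 - w1[["low"]])^2 + (w2[["high"]] - p2)^2)),
    high = min(1, d + sqrt((w1[["high"]] - p1)^2 + (p2 - w2[["low"]])^2)))
}

# Two-sided exact p by summing hypergeometric probabilities of all tables
# with the observed margins whose probability does not exceed the observed
# one (relative tolerance 1e-7, the usual guard against ties lost to
# floating point).
.fisher_p_two_sided <- function(k1, n1, k2, n2) {
  m <- k1 + k2
  if (m == 0 || m == n1 + n2) return(1.0)
  support <- max(0, m - n2):min(n1, m)
  probs <- stats::dhyper(support, m, n1 + n2 - m, n1)
  p_obs <- stats::dhyper(k1, m, n1 + n2 - m, n1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Exact test for a difference between two proportions
#'
#' @param k1,n1,k2,n2 successes and totals for the two samples.
#' @param conf confidence level for the Newcombe-Wilson interval.
#' @param label comparison label carried into reports.
#' @return a one-row data frame of class `proportion_comparison` with
#'   columns `label`, `k1`, `n1`, `k2`, `n2`, `p1`, `p2`, `diff`, `ci_low`,
#'   `ci_high`, `p_value`, `conf`.
#' @export
fisher_exact_two_proportions <- function(k1, n1, k2, n2, conf = 0.95,
                                         label = "") {
  for (v in list(k1, n1, k2, n2))
    if (v < 0 || v != round(v)) stop("counts must be non-negative integers",
                                     call. = FALSE)
  if (k1 > n1 || k2 > n2) stop("k must not exceed n", call. = FALSE)
  ci <- newcombe_diff_interval(k1, n1, k2, n2, conf)
  out <- data.frame(label = label, k1 = k1, n1 = n1, k2 = k2, n2 = n2,
                    p1 = k1 / n1, p2 = k2 / n2, diff = k1 / n1 - k2 / n2,
                    ci_low = ci[["low"]], ci_high = ci[["high"]],
                    p_value = .fisher_p_two_sided(k1, n1, k2, n2),
                    conf = conf, stringsAsFactors = FALSE)
  class(out) <- c("proportion_comparison", "data.frame")
  out
}

#' Monte-Carlo permutation p-value for a difference of proportions
#'
#' Cross-check for the exact conditional test: permutes the k1 + k2 success
#' labels over the n1 + n2 reads (equivalently, draws from the
#' hypergeometric null) and counts tables at least as improbable as the one
#' observed.
#'
#' @param k1,n1,k2,n2 counts as in [fisher_exact_two_proportions()].
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return estimated two-sided p-value.
#' @export
permutation_two_proportions <- function(k1, n1, k2, n2, n_perm = 10000,
                                        seed = 1) {
  set.seed(seed)
  m <- k1 + k2
  if (m == 0 || m == n1 + n2) return(1.0)
  draws <- stats::rhyper(n_perm, m, n1 + n2 - m, n1)
  p_obs <- stats::dhyper(k1, m, n1 + n2 - m, n1)
  mean(stats::dhyper(draws, m, n1 + n2 - m, n1) <= p_obs * (1 + 1e-7))
}

#' Per-genus two-sample screen over a guild
#'
#' One exact two-proportion comparison per guild genus between two samples:
#' k = reads assigned to the genus, n = total (root) reads. Output is sorted
#' by difference in proportions, descending, and flagged significant at
#' `alpha` after the chosen multiple-testing correction.
#'
#' @param table a `taxon_count_table`.
#' @param guild a `guild_definition`.
#' @param sample_a,sample_b sample names present in the table.
#' @param alpha significance level.
#' @param correction `"none"` or `"bh"` (Benjamini-Hochberg).
#' @param conf confidence level for intervals.
#' @param policy a [name_match_policy()].
#' @return data frame of `proportion_comparison` rows plus `p_adjusted` and
#'   `significant` columns, one row per guild genus.
#' @export
per_genus_screen <- function(table, guild = default_guild(), sample_a,
                             sample_b, alpha = 0.05,
                             correction = c("none", "bh"), conf = 0.95,
                             policy = name_match_policy()) {
  correction <- match.arg(correction)
  .check_samples(table, c(sample_a, sample_b))
  root <- .root_counts(table)
  rows <- .genus_rows(table)
  labels <- table$taxa$taxon[rows]
  mapping <- match_genus_names(labels, guild, policy)
  counts_of <- function(sample) {
    k <- stats::setNames(numeric(length(mapping)), names(mapping))
    present <- !is.na(mapping)
    k[present] <- table$counts[rows[match(mapping[present], labels)], sample]
    k
  }
  ka <- counts_of(sample_a); kb <- counts_of(sample_b)
  res <- do.call(rbind, lapply(names(mapping), function(g)
    fisher_exact_two_proportions(ka[[g]], root[[sample_a]],
                                 kb[[g]], root[[sample_b]],
                                 conf = conf, label = g)))
  res$p_adjusted <- if (correction == "bh")
    stats::p.adjust(res$p_value, method = "BH") else res$p_value
  res$significant <- res$p_adjusted < alpha
  res[order(res$diff, decreasing = TRUE), , drop = FALSE]
}

#' Guild-level two-sample test
#'
#' Collapses the table to "hydrocarbon biodegradation guild" vs "others":
#' k = summed reads of all guild genera, n = total reads, per sample. By
#' construction `100 * p1` and `100 * p2` equal the two samples' EIHE
#' values.
#'
#' @inheritParams per_genus_screen
#' @return a one-row `proportion_comparison` labelled `"guild"`.
#' @export
guild_level_test <- function(table, guild = default_guild(), sample_a,
                             sample_b, conf = 0.95,
                             policy = name_match_policy()) {
  .check_samples(table, c(sample_a, sample_b))
  res <- compute_eihe(table, guild, policy)
  root <- .root_counts(table)
  v <- eihe_values(res)
  k <- round(v / 100 * root[names(v)])
  fisher_exact_two_proportions(k[[sample_a]], root[[sample_a]],
                               k[[sample_b]], root[[sample_b]],
                               conf = conf, label = "guild")
}

.check_samples <- function(table, samples) {
  missing <- setdiff(samples, table$sample_names)
  if (length(missing))
    stop("unknown sample name: ", paste(missing, collapse = ", "),
         call. = FALSE)
}

#' Welch's unequal-variance t-test for two replicated groups
#'
#' @param group_a,group_b numeric vectors of per-replicate values (percent
#'   abundances or index values), each of length >= 2.
#' @param label comparison label.
#' @return list of class `group_comparison` with `label`, `statistic`
#'   (Welch t), `df`, `p_value`, `group_values`.
#' @export
welch_t <- function(group_a, group_b, label = "") {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    # zero-variance degenerate case: identical means are indistinguishable
    # (p = 1); different means are separated with certainty (p = 0)
    same <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    return(structure(list(label = label, statistic = if (same) 0 else Inf,
                          df = NA_real_, p_value = if (same) 1 else 0,
                          group_values = list(group_a, group_b),
                          pairwise = NULL),
                     class = "group_comparison"))
  }
  fit <- stats::t.test(group_a, group_b, var.equal = FALSE)
  structure(list(label = label, statistic = unname(fit$statistic),
                 df = unname(fit$parameter), p_value = fit$p.value,
                 group_values = list(group_a, group_b), pairwise = NULL),
            class = "group_comparison")
}

#' Kruskal-Wallis rank test with optional Dunn post-hoc comparisons
#'
#' H statistic with tie correction and a chi-square reference with
#' (groups - 1) degrees of freedom. With `posthoc = TRUE`, Dunn-type
#' pairwise z comparisons on mean ranks, Bonferroni-adjusted.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups).
#' @param posthoc run pairwise Dunn comparisons.
#' @param label comparison label.
#' @return list of class `group_comparison`; `pairwise` is a data frame
#'   with columns `group_a`, `group_b`, `z`, `p_adjusted` when requested.
#' @export
kruskal_wallis <- function(groups, posthoc = FALSE, label = "") {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) == 0)) stop("empty group", call. = FALSE)
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L) {
    res <- list(statistic = 0, p.value = 1)
  } else {
    fit <- stats::kruskal.test(x, g)
    res <- list(statistic = unname(fit$statistic), p.value = fit$p.value)
  }
  pairwise <- NULL
  if (posthoc) pairwise <- .dunn_pairwise(x, g, names(groups))
  structure(list(label = label, statistic = res$statistic,
                 p_value = res$p.value, group_values = groups,
                 pairwise = pairwise),
            class = "group_comparison")
}

# Dunn's z on mean ranks with the tie-corrected variance
# sigma^2 = (N(N+1)/12 - sum(t^3 - t)/(12(N-1))) * (1/ni + 1/nj)
.dunn_pairwise <- function(x, g, group_names = NULL) {
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(r, g, mean)
  n <- tabulate(g)
  levels_g <- levels(g)
  if (is.null(group_names)) group_names <- levels_g
  pairs <- utils::combn(seq_along(levels_g), 2)
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    s2 <- (N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j])
    (mean_rank[[i]] - mean_rank[[j]]) / sqrt(s2)
  })
  p <- stats::p.adjust(2 * stats::pnorm(-abs(z)), method = "bonferroni")
  data.frame(group_a = group_names[pairs[1, ]],
             group_b = group_names[pairs[2, ]],
             z = z, p_adjusted = p, stringsAsFactors = FALSE)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n",
              if (nzchar(x$label)) x$label else "group comparison",
              x$statistic, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("Pairwise (Dunn, Bonferroni-adjusted):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
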