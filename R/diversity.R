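#' Alpha-diversity estimators on OTU count vectors
#'
#' Inputs begin at per-sample OTU abundance vectors (reads per observed OTU,
#' all counts >= 1); clustering, alignment and chimera removal happen
#' upstream in external pipelines. The estimators mirror a standard amplicon
#' survey table: reads, Good's coverage, observed OTUs, Chao1 richness with
#' a log-normal confidence interval, Shannon diversity with its analytic
#' variance, and the percent held by the most abundant OTU — optionally
#' after subsampling all samples to a common depth.
#'
#' @name alpha-diversity
NULL

.check_otu_vector <- function(counts) {
  if (!length(counts) || any(counts < 1 | counts != round(counts)))
    stop("OTU counts must be positive integers", call. = FALSE)
  invisible(counts)
}

#' Good's coverage
#'
#' 100 * (1 - f1/N): the estimated percent probability that one more read
#' would fall in an already-observed OTU (f1 = singletons, N = reads).
#'
#' @param counts integer vector of reads per observed OTU.
#' @return coverage in percent.
#' @export
goods_coverage <- function(counts) {
  .check_otu_vector(counts)
  100 * (1 - sum(counts == 1) / sum(counts))
}

#' Chao1 richness estimator with confidence interval
#'
#' Bias-corrected form (default): S_obs + f1(f1-1)/(2(f2+1)). Classic form:
#' S_obs + f1^2/(2 f2), defined only when doubletons exist. The confidence
#' interval uses the log-normal construction on T = estimate - S_obs:
#' K = exp(z * sqrt(log(1 + var(T)/T^2))), CI = \[S_obs + T/K, S_obs + T*K\],
#' with the variance formula matching the chosen form; when T = 0 the CI
#' collapses to \[S_obs, S_obs\].
#'
#' @param counts integer vector of reads per observed OTU.
#' @param bias_corrected use the bias-corrected estimator (default) or the
#'   classic one.
#' @param conf confidence level.
#' @return list with `estimate`, `ci_low`, `ci_high`, `s_obs`, `f1`, `f2`,
#'   `variance`, `form`.
#' @export
chao1 <- function(counts, bias_corrected = TRUE, conf = 0.95) {
  .check_otu_vector(counts)
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    T_ <- f1 * (f1 - 1) / (2 * (f2 + 1))
    v <- f1 * (f1 - 1) / (2 * (f2 + 1)) +
      f1 * (2 * f1 - 1)^2 / (4 * (f2 + 1)^2) +
      f1^2 * f2 * (f1 - 1)^2 / (4 * (f2 + 1)^4)
    form <- "bias-corrected"
  } else {
    if (f2 == 0)
      stop("classic Chao1 requires doubletons (f2 > 0); use the bias-corrected form",
           call. = FALSE)
    r <- f1 / f2
    T_ <- f1^2 / (2 * f2)
    v <- f2 * (r^2 / 2 + r^3 + r^4 / 4)
    form <- "classic"
  }
  est <- s_obs + T_
  if (T_ == 0) ci <- c(s_obs, s_obs)
  else {
    z <- stats::qnorm((1 + conf) / 2)
    K <- exp(z * sqrt(log(1 + v / T_^2)))
    ci <- c(s_obs + T_ / K, s_obs + T_ * K)
  }
  list(estimate = est, ci_low = ci[1], ci_high = ci[2], s_obs = s_obs,
       f1 = f1, f2 = f2, variance = v, form = form)
}

#' Shannon diversity index with confidence interval
#'
#' H = -sum p_i log p_i, natural log by default (`base` switches it). The
#' interval is H +/- z * sqrt(var) with the analytic variance
#' (sum p (log p)^2 - H^2)/N + (S_obs - 1)/(2 N^2), computed in the chosen
#' base.
#'
#' @param counts integer vector of reads per observed OTU.
#' @param conf confidence level.
#' @param base logarithm base (e for nats, 2 for bits).
#' @return list with `estimate`, `ci_low`, `ci_high`, `variance`.
#' @export
shannon <- function(counts, conf = 0.95, base = exp(1)) {
  .check_otu_vector(counts)
  N <- sum(counts)
  p <- counts / N
  lp <- log(p, base = base)
  H <- -sum(p * lp)
  v <- (sum(p * lp^2) - H^2) / N + (length(counts) - 1) / (2 * N^2)
  z <- stats::qnorm((1 + conf) / 2)
  hw <- z * sqrt(max(v, 0))
  list(estimate = H, ci_low = max(0, H - hw), ci_high = H + hw, variance = v)
}

#' Subsample an OTU vector to a fixed depth
#'
#' Draws `depth` reads without replacement (multivariate hypergeometric) and
#' drops OTUs reduced to zero. Deterministic for a fixed seed.
#'
#' @param counts integer vector of reads per observed OTU.
#' @param depth number of reads to keep; must not exceed the total.
#' @param seed RNG seed.
#' @return integer vector of subsampled counts (all >= 1).
#' @export
subsample_otus <- function(counts, depth, seed = 1) {
  .check_otu_vector(counts)
  N <- sum(counts)
  if (depth > N) stop("subsampling depth exceeds total reads", call. = FALSE)
  if (depth == N) return(counts)
  set.seed(seed)
  drawn <- sample(rep.int(seq_along(counts), counts), depth)
  out <- tabulate(drawn, nbins = length(counts))
  out[out > 0]
}

#' Alpha-diversity report for one sample
#'
#' Computes the full summary on the (optionally subsampled) vector: reads,
#' Good's coverage, S_obs, Chao1 with CI, Shannon with CI, and the percent
#' of reads in the most abundant OTU.
#'
#' @param counts integer vector of reads per observed OTU.
#' @param depth optional subsampling depth applied before all estimators.
#' @param seed RNG seed for subsampling.
#' @param bias_corrected,conf,base passed to [chao1()] and [shannon()].
#' @return object of class `diversity_report`.
#' @export
diversity_report <- function(counts, depth = NULL, seed = 1,
                             bias_corrected = TRUE, conf = 0.95,
                             base = exp(1)) {
  .check_otu_vector(counts)
  if (!is.null(depth)) counts <- subsample_otus(counts, depth, seed)
  ch <- chao1(counts, bias_corrected = bias_corrected, conf = conf)
  sh <- shannon(counts, conf = conf, base = base)
  structure(list(
    reads = sum(counts),
    coverage = goods_coverage(counts),
    s_obs = length(counts),
    chao1 = ch,
    shannon = sh,
    max_otu_percent = 100 * max(counts) / sum(counts),
    subsampled_to = depth,
    chao1_form = ch$form
  ), class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat(sprintf("Reads: %d%s\n", x$reads,
              if (is.null(x$subsampled_to)) "" else
                sprintf(" (subsampled to %d)", x$subsampled_to)))
  cat(sprintf("Coverage: %.1f%%\n", x$coverage))
  cat(sprintf("S_obs: %d\n", x$s_obs))
  cat(sprintf("Chao1 (%s): %.0f (%.0f-%.0f)\n", x$chao1_form,
              x$chao1$estimate, x$chao1$ci_low, x$chao1$ci_high))
  cat(sprintf("Shannon H: %.2f (%.2f-%.2f)\n",
              x$shannon$estimate, x$shannon$ci_low, x$shannon$ci_high))
  cat(sprintf("Most abundant OTU: %.1f%%\n", x$max_otu_percent))
  invisible(x)
}

#' Read per-sample OTU count vectors from a TSV
#'
#' Accepts either a one-column-per-sample table of counts (zeros allowed and
#' dropped per sample) or a mothur `.shared`-style row layout (`label`,
#' `Group`, `numOtus`, then counts).
#'
#' @param path file path or connection.
#' @return named list of integer vectors, one per sample.
#' @export
read_otu_counts <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(first) >= 3 && tolower(first[1]) == "label" &&
      tolower(first[2]) %in% c("group", "sample")) {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    counts <- as.matrix(tab[, -(1:3), drop = FALSE])
    out <- lapply(seq_len(nrow(counts)), function(i) {
      v <- as.numeric(counts[i, ]); v[v > 0]
    })
    names(out) <- tab[[2]]
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    num <- vapply(tab, is.numeric, TRUE)
    out <- lapply(tab[num], function(v) v[v > 0])
  }
  for (v in out) .check_otu_vector(v)
  out
}
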