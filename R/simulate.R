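#' Synthetic two-condition amplicon studies with known ground truth
#'
#' Emulates a pristine-vs-polluted sediment survey at the level the index
#' operates on: genus count tables. A base genus composition is drawn from a
#' symmetric Dirichlet, a designated guild subset is rescaled to a chosen
#' baseline proportion, the polluted condition multiplies the guild genera
#' by an enrichment fold and renormalizes (compositional closure makes the
#' realized fold slightly smaller than the nominal one, so the
#' post-renormalization truth is what gets recorded), and each sample is a
#' multinomial draw at the chosen sequencing depth. An optional
#' Dirichlet-multinomial mode adds per-sample overdispersion for robustness
#' checks.
#'
#' @name simulation
NULL

#' Specification of a simulated two-condition community study
#'
#' @param n_genera number of genera in the community.
#' @param guild_size number of genera designated as the guild
#'   (`<= n_genera`).
#' @param baseline_concentration symmetric Dirichlet concentration for the
#'   base composition draw.
#' @param guild_baseline total expected guild proportion in the pristine
#'   condition (0-1); the drawn composition is rescaled to honour it.
#' @param enrichment_fold multiplicative enrichment of guild genera in the
#'   polluted condition (>= 1; 1 encodes the null).
#' @param depth reads per sample.
#' @param n_per_group samples per condition.
#' @param overdispersion optional per-sample Dirichlet-multinomial
#'   concentration scale; `NULL` (default) draws plain multinomials.
#' @param seed RNG seed; every draw is a pure function of it.
#' @return list of class `community_sim_spec`.
#' @export
community_sim_spec <- function(n_genera = 500, guild_size = 63,
                               baseline_concentration = 1,
                               guild_baseline = 0.01, enrichment_fold = 4,
                               depth = 25000, n_per_group = 1,
                               overdispersion = NULL, seed = 1) {
  if (guild_size < 1 || guild_size > n_genera)
    stop("guild_size must lie in [1, n_genera]", call. = FALSE)
  if (enrichment_fold < 1) stop("enrichment_fold must be >= 1", call. = FALSE)
  if (guild_baseline <= 0 || guild_baseline >= 1)
    stop("guild_baseline must lie in (0, 1)", call. = FALSE)
  structure(list(n_genera = n_genera, guild_size = guild_size,
                 baseline_concentration = baseline_concentration,
                 guild_baseline = guild_baseline,
                 enrichment_fold = enrichment_fold, depth = depth,
                 n_per_group = n_per_group, overdispersion = overdispersion,
                 seed = seed),
            class = "community_sim_spec")
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a pristine-vs-polluted genus count study
#'
#' @param spec a [community_sim_spec()].
#' @return list of class `simulated_study`: `table` (a
#'   `taxon_count_table`), `guild` (the designated genera as a
#'   `guild_definition`), `truth` (expected guild proportions and EIHE per
#'   condition, post-renormalization, plus their ratio), `groups` (named
#'   condition per sample) and `spec`.
#' @export
simulate_two_group_study <- function(spec = community_sim_spec()) {
  stopifnot(inherits(spec, "community_sim_spec"))
  set.seed(spec$seed)
  genera <- sprintf("Genus%04d", seq_len(spec$n_genera))
  guild_idx <- seq_len(spec$guild_size)
  base <- .rdirichlet(rep(spec$baseline_concentration, spec$n_genera))
  # rescale so the guild holds exactly guild_baseline of the community
  base[guild_idx] <- base[guild_idx] / sum(base[guild_idx]) * spec$guild_baseline
  base[-guild_idx] <- if (spec$guild_size < spec$n_genera)
    base[-guild_idx] / sum(base[-guild_idx]) * (1 - spec$guild_baseline) else 0
  polluted <- base
  polluted[guild_idx] <- polluted[guild_idx] * spec$enrichment_fold
  polluted <- polluted / sum(polluted)
  draw <- function(prob) {
    if (!is.null(spec$overdispersion))
      prob <- .rdirichlet(prob * spec$overdispersion)
    stats::rmultinom(1, spec$depth, prob)[, 1]
  }
  ns <- spec$n_per_group
  samples <- c(paste0("pristine_", seq_len(ns)), paste0("polluted_", seq_len(ns)))
  counts <- cbind(
    matrix(vapply(seq_len(ns), function(i) draw(base), numeric(spec$n_genera)),
           ncol = ns),
    matrix(vapply(seq_len(ns), function(i) draw(polluted), numeric(spec$n_genera)),
           ncol = ns))
  colnames(counts) <- samples
  tab <- genus_matrix_table(counts, genera)
  guild <- guild_definition(
    data.frame(genus = genera[guild_idx], stringsAsFactors = FALSE),
    name = "simulated-guild", version = "1.0.0")
  p_pristine <- sum(base[guild_idx])
  p_polluted <- sum(polluted[guild_idx])
  structure(list(
    table = tab, guild = guild,
    truth = list(prop_pristine = p_pristine, prop_polluted = p_polluted,
                 eihe_pristine = 100 * p_pristine,
                 eihe_polluted = 100 * p_polluted,
                 eihe_ratio = p_polluted / p_pristine),
    groups = stats::setNames(rep(c("pristine", "polluted"), each = ns), samples),
    spec = spec
  ), class = "simulated_study")
}

#' Simulate an OTU count vector from a known community
#'
#' @param true_richness number of OTUs in the underlying community.
#' @param shape abundance model: `"uniform"` (all OTUs equally probable) or
#'   `"logseries"` (probability of OTU i proportional to x^i / i).
#' @param depth reads drawn.
#' @param x log-series parameter in (0, 1); ignored for `"uniform"`.
#' @param seed RNG seed.
#' @return list with `counts` (observed OTU vector, positives only) and
#'   `truth` (list with `true_richness`, `shape`).
#' @export
simulate_otu_vector <- function(true_richness, shape = c("uniform", "logseries"),
                                depth = 25000, x = 0.99, seed = 1) {
  shape <- match.arg(shape)
  if (true_richness < 1 || depth < 1)
    stop("true_richness and depth must be >= 1", call. = FALSE)
  prob <- switch(shape,
    uniform = rep(1 / true_richness, true_richness),
    logseries = {
      if (x <= 0 || x >= 1)
        stop("log-series parameter x must lie in (0, 1)", call. = FALSE)
      w <- x^seq_len(true_richness) / seq_len(true_richness)
      w / sum(w)
    })
  set.seed(seed)
  draw <- stats::rmultinom(1, depth, prob)[, 1]
  list(counts = draw[draw > 0],
       truth = list(true_richness = true_richness, shape = shape))
}

#' Write a simulated study as a mothur-dialect taxonomy summary
#'
#' Emits a syntactically valid `.tax.summary` (root row plus a flat genus
#' layer) that [read_mothur_tax_summary()] reads back with zero loss.
#'
#' @param study a `simulated_study` (or any two-level `taxon_count_table`
#'   passed via `table`).
#' @param path output file path.
#' @export
write_fixture_tax_summary <- function(study, path) {
  tab <- if (inherits(study, "simulated_study")) study$table else study
  stopifnot(inherits(tab, "taxon_count_table"))
  counts <- tab$counts
  header <- paste(c("taxlevel", "rankID", "taxon", "daughterlevels", "total",
                    tab$sample_names), collapse = "\t")
  body <- vapply(seq_len(nrow(tab$taxa)), function(i)
    paste(c(tab$taxa$tax_level[i], tab$taxa$rank_id[i], tab$taxa$taxon[i],
            tab$taxa$daughter_levels[i], sum(counts[i, ]),
            format(counts[i, ], scientific = FALSE, trim = TRUE)),
          collapse = "\t"), "")
  .write_lines(c(header, body), path)
}

#' Export a simulated study's ground truth as JSON
#'
#' @param study a `simulated_study`.
#' @param path output file path.
#' @export
write_truth_json <- function(study, path) {
  stopifnot(inherits(study, "simulated_study"))
  jsonlite::write_json(
    list(truth = study$truth, groups = as.list(study$groups),
         spec = unclass(study$spec)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
}
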