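#' The ecological index of hydrocarbon exposure
#'
#' The EIHE of a sample is the summed relative abundance, as a percentage of
#' the total reads, of the genera in a hydrocarbon-biodegradation guild:
#' EIHE = sum over guild genera of 100 * (genus reads) / (total reads).
#' It estimates the proportion of the bacterial community potentially capable
#' of degrading hydrocarbons. The denominator is the root (total classified
#' reads) count, not the sum of genus-level rows, so reads unclassified below
#' the root still dilute the index.
#'
#' @name eihe-index
NULL

#' Name-matching policy for genus labels
#'
#' Classifier output labels differ from curated guild spellings in casing and
#' decorations (surrounding quotes, candidate-status markers, bracketed
#' qualifiers). The policy controls how labels are normalized before exact
#' comparison; no fuzzy or substring matching exists.
#'
#' @param case_sensitive compare labels case-sensitively.
#' @param use_synonyms accept a guild entry's synonyms as matches.
#' @param strip_decorations remove surrounding quotes, `Candidatus` markers
#'   and bracketed qualifiers before comparison.
#' @return an object of class `name_match_policy`.
#' @export
name_match_policy <- function(case_sensitive = FALSE, use_synonyms = TRUE,
                              strip_decorations = TRUE) {
  structure(list(case_sensitive = isTRUE(case_sensitive),
                 use_synonyms = isTRUE(use_synonyms),
                 strip_decorations = isTRUE(strip_decorations)),
            class = "name_match_policy")
}

.normalize_label <- function(x, policy) {
  if (policy$strip_decorations) {
    x <- gsub('^["“”\']+|["“”\']+$', "", trimws(x))
    x <- sub("^\\[(.*)\\]$", "\\1", x)        # [Marinobacter] -> Marinobacter
    x <- sub("^Candidatus[ _]+", "", x, ignore.case = TRUE)
    x <- trimws(x)
  }
  if (!policy$case_sensitive) x <- tolower(x)
  x
}

#' Match table genus labels against a guild
#'
#' Deterministically maps each guild genus to at most one table label under
#' the given policy. Two table labels normalizing to the same guild genus is
#' an ambiguity error, never a silent pick.
#'
#' @param table_taxa character vector of genus labels found in a table.
#' @param guild a `guild_definition`.
#' @param policy a [name_match_policy()].
#' @return named character vector over guild genera; `NA` where absent.
#' @export
match_genus_names <- function(table_taxa, guild,
                              policy = name_match_policy()) {
  stopifnot(inherits(guild, "guild_definition"))
  genera <- guild_genera(guild)
  norm_tab <- .normalize_label(table_taxa, policy)
  out <- stats::setNames(rep(NA_character_, length(genera)), genera)
  for (i in seq_along(genera)) {
    keys <- genera[i]
    if (policy$use_synonyms) keys <- c(keys, guild$synonyms[[genera[i]]])
    hits <- which(norm_tab %in% .normalize_label(keys, policy))
    if (length(hits) > 1L)
      stop("ambiguous genus match for guild genus '", genera[i], "': labels ",
           paste(sQuote(table_taxa[hits]), collapse = ", "), call. = FALSE)
    if (length(hits) == 1L) out[i] <- table_taxa[hits]
  }
  out
}

#' Per-sample percent abundances at genus rank
#'
#' @param table a `taxon_count_table` with a designated genus rank.
#' @return list of per-sample profiles, each with `sample_name`,
#'   `total_reads` and `genus_percents` (named numeric, percent of total
#'   reads).
#' @export
percent_abundances <- function(table) {
  stopifnot(inherits(table, "taxon_count_table"))
  root <- .root_counts(table)
  zero <- names(root)[root == 0]
  if (length(zero))
    stop("zero total reads in sample: ", paste(zero, collapse = ", "),
         call. = FALSE)
  rows <- .genus_rows(table)
  lapply(table$sample_names, function(s) {
    pct <- 100 * table$counts[rows, s] / root[[s]]
    list(sample_name = s, total_reads = root[[s]],
         genus_percents = stats::setNames(pct, table$taxa$taxon[rows]))
  })
}

#' Compute EIHE values with per-genus contributions
#'
#' For each sample, sums the percent abundances of the guild genera present
#' in the table; absent genera contribute 0 but are reported, so the
#' contribution table always covers the whole guild.
#'
#' @param table a `taxon_count_table`.
#' @param guild a `guild_definition`; defaults to the packaged 63-genus list.
#' @param policy a [name_match_policy()].
#' @return object of class `eihe_results`: a list with one entry per sample
#'   (`sample_name`, `eihe`, `contributions`, `matched`, `unmatched`) plus
#'   attributes `guild_name` and `guild_version`.
#' @examples
#' counts <- data.frame(S1 = c(30, 20, 950))
#' tab <- genus_matrix_table(counts, c("Alcanivorax", "Marinobacter", "OtherX"))
#' res <- compute_eihe(tab)
#' res[[1]]$eihe  # 5.0
#' @export
compute_eihe <- function(table, guild = default_guild(),
                         policy = name_match_policy()) {
  profiles <- percent_abundances(table)
  rows <- .genus_rows(table)
  labels <- table$taxa$taxon[rows]
  mapping <- match_genus_names(labels, guild, policy)
  matched <- names(mapping)[!is.na(mapping)]
  unmatched <- names(mapping)[is.na(mapping)]
  res <- lapply(profiles, function(p) {
    contrib <- stats::setNames(numeric(length(mapping)), names(mapping))
    present <- !is.na(mapping)
    contrib[present] <- p$genus_percents[mapping[present]]
    list(sample_name = p$sample_name, eihe = sum(contrib),
         contributions = contrib, matched = matched, unmatched = unmatched)
  })
  structure(res, class = "eihe_results",
            guild_name = guild$name, guild_version = guild$version)
}

#' EIHE values as a named vector
#' @param results an `eihe_results` object.
#' @return named numeric vector of index values (percent), one per sample.
#' @export
eihe_values <- function(results) {
  stopifnot(inherits(results, "eihe_results"))
  vapply(results, function(r) r$eihe, 0,
         USE.NAMES = FALSE) |> stats::setNames(
           vapply(results, function(r) r$sample_name, ""))
}

#' Per-genus contribution matrix
#' @param results an `eihe_results` object.
#' @return numeric matrix, guild genera x samples, percent of total reads.
#' @export
eihe_contributions <- function(results) {
  stopifnot(inherits(results, "eihe_results"))
  m <- vapply(results, function(r) r$contributions,
              numeric(length(results[[1]]$contributions)))
  m <- matrix(m, ncol = length(results),
              dimnames = list(names(results[[1]]$contributions),
                              vapply(results, function(r) r$sample_name, "")))
  m
}

#' @export
print.eihe_results <- function(x, ...) {
  v <- eihe_values(x)
  cat(sprintf("EIHE (guild '%s' v%s), %d sample(s):\n",
              attr(x, "guild_name"), attr(x, "guild_version"), length(v)))
  print(round(v, 1))
  cat(sprintf("Guild genera matched in table: %d of %d\n",
              length(x[[1]]$matched),
              length(x[[1]]$matched) + length(x[[1]]$unmatched)))
  invisible(x)
}

#' Write the space-delimited index file
#'
#' One line per sample: sample name, a single space, the index value. The
#' default report mode prints one decimal; machine mode prints full
#' precision.
#'
#' @param results an `eihe_results` object.
#' @param path output file path or connection.
#' @param mode `"report"` (one decimal) or `"machine"` (full precision).
#' @export
write_index_file <- function(results, path, mode = c("report", "machine")) {
  stopifnot(inherits(results, "eihe_results"))
  if (length(results) == 0L) stop("no results to write", call. = FALSE)
  mode <- match.arg(mode)
  v <- eihe_values(results)
  txt <- if (mode == "report") sprintf("%.1f", v) else
    format(v, digits = 15, trim = TRUE, scientific = FALSE)
  .write_lines(paste(names(v), txt), path)
}

#' Write the per-genus contribution table
#'
#' TSV with one row per guild genus (zeros included for absent genera), one
#' column per sample, cells in percent of total reads; the final `EIHE` row
#' holds the column sums, i.e. the index values.
#'
#' @param results an `eihe_results` object.
#' @param path output file path or connection.
#' @param mode `"report"` (one decimal) or `"machine"` (full precision).
#' @export
write_contribution_table <- function(results, path,
                                     mode = c("report", "machine")) {
  stopifnot(inherits(results, "eihe_results"))
  if (length(results) == 0L) stop("no results to write", call. = FALSE)
  mode <- match.arg(mode)
  m <- eihe_contributions(results)
  m <- rbind(m, EIHE = colSums(m))
  fmt <- function(x) if (mode == "report") sprintf("%.1f", x) else
    format(x, digits = 15, trim = TRUE, scientific = FALSE)
  lines <- c(paste(c("genus", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t"), ""))
  .write_lines(lines, path)
}

.write_lines <- function(lines, path) {
  if (inherits(path, "connection")) writeLines(lines, path, sep = "\n")
  else {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
  }
  invisible(NULL)
}
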