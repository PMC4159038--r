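#' Hierarchical taxon-by-sample count tables
#'
#' The container behind all index math: read counts per taxon and sample,
#' organized as the hierarchy a taxonomy summary encodes. Each row carries a
#' taxonomic depth (`tax_level`, 0 = root), a dotted-path `rank_id` (e.g.
#' `"0.1.2"`), the taxon name, the number of daughter levels and one integer
#' count per sample. Validity requires exactly one root row, counts bounded
#' by the root count, and hierarchical consistency: every internal row's
#' count equals the sum of its immediate daughters' counts, per sample.
#'
#' @name taxon_count_table
NULL

#' Construct and validate a taxon count table
#'
#' @param taxa data frame with columns `tax_level` (integer), `rank_id`
#'   (character, dotted path), `taxon` (character), `daughter_levels`
#'   (integer).
#' @param counts integer matrix, rows matching `taxa`, one column per sample.
#' @param rank_of_genus taxonomic depth designated as genus level; defaults
#'   to the deepest level present.
#' @return an object of class `taxon_count_table`.
#' @export
taxon_count_table <- function(taxa, counts, rank_of_genus = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) || any(colnames(counts) == ""))
    stop("counts must have sample names as column names", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample names", call. = FALSE)
  if (nrow(taxa) != nrow(counts))
    stop("taxa and counts disagree on row count", call. = FALSE)
  .check_counts_integer(counts)
  storage.mode(counts) <- "double"  # exact for counts < 2^53
  depth <- lengths(strsplit(taxa$rank_id, ".", fixed = TRUE)) - 1L
  if (any(depth != taxa$tax_level))
    stop("rank_id depth disagrees with tax_level for taxon: ",
         paste(utils::head(taxa$taxon[depth != taxa$tax_level], 3), collapse = ", "),
         call. = FALSE)
  root <- which(taxa$tax_level == 0L)
  if (length(root) != 1L) stop("missing root row", call. = FALSE)
  if (any(sweep(counts, 2, counts[root, ]) > 0))
    stop("a taxon count exceeds the root count", call. = FALSE)
  obj <- structure(list(taxa = taxa, counts = counts,
                        sample_names = colnames(counts),
                        rank_of_genus = rank_of_genus %||% max(taxa$tax_level)),
                   class = "taxon_count_table")
  .check_hierarchy(obj)
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_counts_integer <- function(counts) {
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("negative or non-integer count at row %d, sample '%s'",
                 bad[1, 1], colnames(counts)[bad[1, 2]]), call. = FALSE)
  }
}

# Parent of "0.1.2" is "0.1"; root "0" has no parent.
.parent_rank <- function(rank_id) sub("\\.[0-9]+$", "", rank_id)

.check_hierarchy <- function(obj) {
  taxa <- obj$taxa
  internal <- which(taxa$daughter_levels > 0L)
  if (!length(internal)) return(invisible(TRUE))
  parent_of <- .parent_rank(taxa$rank_id)
  for (i in internal) {
    kids <- which(parent_of == taxa$rank_id[i] & taxa$tax_level == taxa$tax_level[i] + 1L)
    if (!length(kids)) next  # daughters not expanded in this file
    kid_sum <- colSums(obj$counts[kids, , drop = FALSE])
    if (any(abs(kid_sum - obj$counts[i, ]) > 0))
      stop(sprintf(
        "hierarchical inconsistency at taxon '%s' (%s): daughters sum to %s, row says %s",
        taxa$taxon[i], taxa$rank_id[i],
        paste(kid_sum, collapse = ","), paste(obj$counts[i, ], collapse = ",")),
        call. = FALSE)
  }
  invisible(TRUE)
}

.root_counts <- function(table) {
  table$counts[which(table$taxa$tax_level == 0L), ]
}

.genus_rows <- function(table) which(table$taxa$tax_level == table$rank_of_genus)

#' Read a mothur-style hierarchical taxonomy summary
#'
#' Parses the tab-delimited `.tax.summary` dialect: header columns
#' `taxlevel`, `rankID`, `taxon`, `daughterlevels`, `total`, then one column
#' per sample. The `total` column is recomputed as the per-sample row sum; a
#' mismatch with the stored value raises a warning, not an error, since
#' hand-edited summaries are common.
#'
#' @param path file path or connection.
#' @param rank_of_genus genus depth; defaults to the deepest level in the file.
#' @return a `taxon_count_table`.
#' @export
read_mothur_tax_summary <- function(path, rank_of_genus = NULL) {
  hdr <- utils::read.delim(path, nrows = 1, header = TRUE,
                           check.names = FALSE, colClasses = "character")
  required <- c("taxlevel", "rankID", "taxon", "daughterlevels", "total")
  if (!all(required %in% names(hdr)))
    stop("not a taxonomy summary: header must contain ",
         paste(required, collapse = ", "), call. = FALSE)
  classes <- ifelse(names(hdr) == "rankID", "character", NA)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = classes, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("missing root row", call. = FALSE)
  sample_cols <- setdiff(names(tab), required)
  if (!length(sample_cols))
    stop("taxonomy summary has no sample columns", call. = FALSE)
  counts <- as.matrix(tab[sample_cols])
  .check_counts_integer(counts)
  row_sum <- rowSums(counts)
  stored <- suppressWarnings(as.numeric(tab$total))
  off <- which(is.na(stored) | abs(stored - row_sum) > 0)
  if (length(off))
    warning(sprintf(
      "'total' column disagrees with per-sample sum for %d row(s) (e.g. taxon '%s'); recomputed totals are used",
      length(off), tab$taxon[off[1]]), call. = FALSE)
  taxa <- data.frame(tax_level = as.integer(tab$taxlevel),
                     rank_id = tab$rankID,
                     taxon = tab$taxon,
                     daughter_levels = as.integer(tab$daughterlevels),
                     stringsAsFactors = FALSE)
  taxon_count_table(taxa, counts, rank_of_genus = rank_of_genus)
}

#' Merge demultiplexed one-sample taxonomy summaries
#'
#' Public archives often hold one summary file per sample. This reads each,
#' takes the union of taxa (absent taxa get count 0) and re-validates the
#' hierarchy of the merged table. Taxa are identified by their `rank_id`
#' path; the same path carrying two different taxon names across files is a
#' conflict.
#'
#' @param paths character vector of file paths, named by sample; unnamed
#'   entries use the single sample column name found in each file.
#' @param rank_of_genus genus depth for the merged table.
#' @return a `taxon_count_table` with one column per input file.
#' @export
read_single_sample_summaries <- function(paths, rank_of_genus = NULL) {
  tabs <- lapply(paths, read_mothur_tax_summary)
  nm <- names(paths)
  if (is.null(nm)) nm <- rep("", length(paths))
  for (i in seq_along(tabs)) {
    if (ncol(tabs[[i]]$counts) != 1L)
      stop("file is not single-sample: ", paths[i], call. = FALSE)
    if (nm[i] == "") nm[i] <- tabs[[i]]$sample_names
  }
  if (anyDuplicated(nm))
    stop("duplicate sample names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  # union of taxa keyed by rank_id, in first-seen order
  key <- character(0); taxa <- NULL
  for (t in tabs) {
    new <- !(t$taxa$rank_id %in% key)
    if (any(new)) {
      taxa <- rbind(taxa, t$taxa[new, ])
      key <- c(key, t$taxa$rank_id[new])
    }
    idx <- match(t$taxa$rank_id, key)
    conflict <- which(taxa$taxon[idx] != t$taxa$taxon)
    if (length(conflict))
      stop("conflicting taxon names for rank path ",
           t$taxa$rank_id[conflict[1]], ": '",
           taxa$taxon[idx[conflict[1]]], "' vs '",
           t$taxa$taxon[conflict[1]], "'", call. = FALSE)
  }
  rownames(taxa) <- NULL
  # the same taxon name under the same parent must keep one rank path
  key2 <- paste(.parent_rank(taxa$rank_id), taxa$tax_level, taxa$taxon)
  if (anyDuplicated(key2)) {
    d <- key2[duplicated(key2)][1]
    stop("conflicting rank paths for taxon '", taxa$taxon[key2 == d][1],
         "' under the same parent: ",
         paste(taxa$rank_id[key2 == d], collapse = " vs "), call. = FALSE)
  }
  counts <- matrix(0, nrow = nrow(taxa), ncol = length(tabs),
                   dimnames = list(NULL, nm))
  for (i in seq_along(tabs))
    counts[match(tabs[[i]]$taxa$rank_id, key), i] <- tabs[[i]]$counts[, 1]
  # recompute daughter_levels: a parent whose daughters are absent in one
  # file keeps its flag; hierarchy check tolerates unexpanded daughters
  taxon_count_table(taxa, counts, rank_of_genus = rank_of_genus)
}

#' Read a generic genus-by-sample count matrix
#'
#' A headered TSV whose first column is genus names and remaining columns are
#' integer counts per sample, turned into a two-level table with a synthetic
#' root equal to the column sums.
#'
#' @param path file path or connection.
#' @return a `taxon_count_table` with genus rank 1.
#' @export
read_genus_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) < 2L) stop("empty genus matrix", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (length(unique(ncols)) != 1L)
    stop(sprintf("ragged row in genus matrix (line %d has %d fields, header has %d)",
                 which(ncols != ncols[1])[1], ncols[ncols != ncols[1]][1], ncols[1]),
         call. = FALSE)
  header <- fields[[1]]
  body <- fields[-1]
  genus <- vapply(body, `[`, "", 1L)
  raw <- vapply(body, function(f) f[-1], character(length(header) - 1L))
  raw <- matrix(raw, ncol = length(header) - 1L, byrow = TRUE,
                dimnames = list(NULL, header[-1]))
  counts <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                    dimnames = dimnames(raw)))
  .check_counts_integer(counts)
  genus_matrix_table(stats::setNames(as.data.frame(counts), colnames(counts)),
                     genus)
}

#' Build a two-level taxon count table from genus counts
#'
#' @param counts data frame or matrix of counts (genera x samples).
#' @param genus character vector of genus names, one per row.
#' @param root_name taxon name for the synthetic root row.
#' @return a `taxon_count_table`.
#' @export
genus_matrix_table <- function(counts, genus, root_name = "Root") {
  counts <- as.matrix(counts)
  if (anyDuplicated(genus)) stop("duplicate genus rows", call. = FALSE)
  taxa <- data.frame(
    tax_level = c(0L, rep(1L, length(genus))),
    rank_id = c("0", paste0("0.", seq_along(genus))),
    taxon = c(root_name, genus),
    daughter_levels = c(1L, rep(0L, length(genus))),
    stringsAsFactors = FALSE)
  full <- rbind(colSums(counts), counts)
  rownames(full) <- NULL
  taxon_count_table(taxa, full, rank_of_genus = 1L)
}

#' @export
print.taxon_count_table <- function(x, ...) {
  cat(sprintf("Taxon count table: %d taxa (genus rank %d), %d sample(s)\n",
              nrow(x$taxa), x$rank_of_genus, length(x$sample_names)))
  root <- .root_counts(x)
  cat("Total reads per sample:\n")
  print(root)
  invisible(x)
}
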