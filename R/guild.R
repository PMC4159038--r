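#' Guild definitions: sets of genera sharing a functional role
#'
#' A guild definition is the membership list behind the index: the genera
#' whose summed relative abundance constitutes the EIHE. Each entry carries a
#' genus name, its phylum, the isolation environment of described
#' hydrocarbon-degrading strains (`marine`, `terrestrial`, `both` or
#' `unknown`), free-text evidence notes and optional synonyms accepted during
#' name matching. Genus names are unique case-insensitively; stored
#' capitalization is preserved.
#'
#' @name guild
NULL

.valid_environments <- c("marine", "terrestrial", "both", "unknown")

#' Construct a guild definition from a data frame of entries
#'
#' @param entries data frame with columns `genus` (required), and optionally
#'   `phylum`, `isolation_environment`, `synonyms` (semicolon-separated
#'   string), `evidence_note`.
#' @param name short label for the guild.
#' @param version version string recorded in outputs.
#' @return an object of class `guild_definition`.
#' @export
guild_definition <- function(entries, name = "custom", version = "1.0.0") {
  if (!is.data.frame(entries) || nrow(entries) == 0L)
    stop("empty guild list", call. = FALSE)
  if (!"genus" %in% names(entries))
    stop("guild table must have a 'genus' column", call. = FALSE)
  genus <- trimws(as.character(entries$genus))
  if (any(is.na(genus) | genus == ""))
    stop("guild entries must have non-empty genus names", call. = FALSE)
  dup <- genus[duplicated(tolower(genus))]
  if (length(dup))
    stop("duplicate genus in guild list: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  phylum <- if ("phylum" %in% names(entries)) as.character(entries$phylum) else
    rep(NA_character_, length(genus))
  phylum[is.na(phylum) | trimws(phylum) == ""] <- "unknown"
  env <- if ("isolation_environment" %in% names(entries))
    as.character(entries$isolation_environment) else rep("unknown", length(genus))
  env[is.na(env) | trimws(env) == ""] <- "unknown"
  bad <- setdiff(unique(env), .valid_environments)
  if (length(bad))
    stop("invalid isolation_environment value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  syn_raw <- if ("synonyms" %in% names(entries)) as.character(entries$synonyms) else
    rep("", length(genus))
  syn_raw[is.na(syn_raw)] <- ""
  synonyms <- lapply(strsplit(syn_raw, ";", fixed = TRUE), function(s) {
    s <- trimws(s)
    s[s != ""]
  })
  all_syn <- tolower(unlist(synonyms))
  clash <- intersect(all_syn, tolower(genus))
  if (length(clash))
    stop("synonym collides with a guild genus name: ",
         paste(unique(clash), collapse = ", "), call. = FALSE)
  note <- if ("evidence_note" %in% names(entries))
    as.character(entries$evidence_note) else rep("", length(genus))
  note[is.na(note)] <- ""
  structure(list(
    name = name,
    version = version,
    entries = data.frame(genus = genus, phylum = trimws(phylum),
                         isolation_environment = trimws(env),
                         evidence_note = note, stringsAsFactors = FALSE),
    synonyms = stats::setNames(synonyms, genus)
  ), class = "guild_definition")
}

#' Load a guild definition from a delimited text file
#'
#' Reads a headered delimited table (tab by default; `#` lines are comments)
#' with at least a `genus` column. A `dialect` mapping renames user columns to
#' the canonical ones, e.g. `c(genus = "Genus_name")` if the file calls its
#' genus column `Genus_name`. Rows missing a phylum are recorded as
#' `"unknown"`.
#'
#' @param path file path or connection.
#' @param dialect optional named character vector mapping canonical column
#'   names (`genus`, `phylum`, `isolation_environment`, `synonyms`,
#'   `evidence_note`) to the column names used in the file.
#' @param sep field separator.
#' @param name,version passed to [guild_definition()].
#' @return a `guild_definition`.
#' @export
load_guild_list <- function(path, dialect = NULL, sep = "\t",
                            name = "custom", version = "1.0.0") {
  tab <- tryCatch(
    utils::read.delim(path, sep = sep, comment.char = "#",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character"),
    error = function(e) stop("empty guild list", call. = FALSE))
  if (nrow(tab) == 0L) stop("empty guild list", call. = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      if (!dialect[[canon]] %in% names(tab))
        stop("dialect column not found in file: ", dialect[[canon]],
             call. = FALSE)
      names(tab)[names(tab) == dialect[[canon]]] <- canon
    }
  }
  guild_definition(tab, name = name, version = version)
}

#' The packaged default hydrocarbon-biodegradation guild
#'
#' Returns the 63-genus hydrocarbon-biodegradation guild shipped with the
#' package: genera with at least one described hydrocarbon-degrading strain,
#' spanning Proteobacteria (71.4%), Actinobacteria (19.0%), Bacteroidetes
#' (4.8%) and Firmicutes (4.8%). The list is a curated, replaceable data
#' asset (see the file header in `inst/extdata/hydrocarbon_guild.tsv`);
#' [extend_guild()] adds candidate genera as evidence accumulates.
#'
#' @return a `guild_definition` with 63 entries.
#' @export
default_guild <- function() {
  path <- system.file("extdata", "hydrocarbon_guild.tsv", package = "eihe",
                      mustWork = TRUE)
  load_guild_list(path, name = "hydrocarbon-biodegradation",
                  version = "1.0.0")
}

#' Phylum composition of a guild
#'
#' @param guild a `guild_definition`.
#' @return named numeric vector: percent of entries per phylum, one decimal,
#'   sorted decreasing.
#' @export
phylum_composition <- function(guild) {
  stopifnot(inherits(guild, "guild_definition"))
  n <- table(guild$entries$phylum)
  pct <- round(100 * as.numeric(n) / sum(n), 1)
  sort(stats::setNames(pct, names(n)), decreasing = TRUE)
}

#' Number of genera in a guild
#' @param guild a `guild_definition`.
#' @return integer count of entries.
#' @export
guild_size <- function(guild) nrow(guild$entries)

#' Genus names of a guild
#' @param guild a `guild_definition`.
#' @return character vector of genus names in file order.
#' @export
guild_genera <- function(guild) guild$entries$genus

#' Extend a guild with additional genera
#'
#' Returns a new definition with the additions appended and a bumped version;
#' the original is unchanged. Additions colliding (case-insensitively) with
#' existing entries or their synonyms are an error.
#'
#' @param guild a `guild_definition`.
#' @param additions data frame with the same columns as accepted by
#'   [guild_definition()]; may have zero rows.
#' @return a new `guild_definition`.
#' @export
extend_guild <- function(guild, additions) {
  stopifnot(inherits(guild, "guild_definition"))
  old <- guild$entries
  old$synonyms <- vapply(guild$synonyms, paste, "", collapse = ";")
  if (is.null(additions) || nrow(additions) == 0L) new <- old
  else {
    add <- additions
    for (col in c("phylum", "isolation_environment", "synonyms", "evidence_note"))
      if (!col %in% names(add)) add[[col]] <- ""
    new <- rbind(old[c("genus", "phylum", "isolation_environment", "synonyms",
                       "evidence_note")],
                 add[c("genus", "phylum", "isolation_environment", "synonyms",
                       "evidence_note")])
  }
  version <- .bump_version(guild$version)
  guild_definition(new, name = guild$name, version = version)
}

.bump_version <- function(v) {
  parts <- strsplit(v, ".", fixed = TRUE)[[1]]
  n <- suppressWarnings(as.integer(parts))
  if (length(n) && !anyNA(n)) {
    n[length(n)] <- n[length(n)] + 1L
    paste(n, collapse = ".")
  } else paste0(v, "+1")
}

#' Write a guild definition to a TSV file
#'
#' Inverse of [load_guild_list()]: the written file round-trips membership,
#' phyla, environments, synonyms and notes exactly.
#'
#' @param guild a `guild_definition`.
#' @param path output file path.
#' @export
write_guild_list <- function(guild, path) {
  stopifnot(inherits(guild, "guild_definition"))
  out <- guild$entries
  out$synonyms <- vapply(guild$synonyms, paste, "", collapse = ";")
  out <- out[c("genus", "phylum", "isolation_environment", "synonyms",
               "evidence_note")]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# Guild: %s, version %s", guild$name, guild$version), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @export
print.guild_definition <- function(x, ...) {
  cat(sprintf("Guild definition '%s' (version %s): %d genera\n",
              x$name, x$version, nrow(x$entries)))
  comp <- phylum_composition(x)
  cat("Phylum composition: ",
      paste(sprintf("%s %.1f%%", names(comp), comp), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
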