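# ---- SILVA accession -> NCBI taxon id mapping ------------------------------
#
# The mapping ("synonym") file lets an importer resolve the accession of a
# BLAST hit directly to an NCBI taxon, so SILVA records never need editing.
# Matching order: exact full-name lookup; blocked names (uncultured /
# unidentified / metagenome) fall through to a climb of the taxonomic path
# from its lowest element, skipping path elements that mention
# "environmental samples"; unmatched names get a capitalization retry.

#' Default blocked keywords
#'
#' Keyword matching is case-insensitive substring containment, applied to the
#' organism full name (`name_keywords`) and to taxonomic-path elements
#' (`path_keywords`).
#'
#' @param name_keywords keywords that force the path search instead of a
#'   full-name match.
#' @param path_keywords keywords that make a path element unusable.
#' @return a `blocked_keywords` object.
#' @export
blocked_keywords <- function(name_keywords = c("uncultured", "unidentified",
                                               "metagenome"),
                             path_keywords = "environmental samples") {
  structure(list(name_keywords = tolower(name_keywords),
                 path_keywords = tolower(path_keywords)),
            class = "blocked_keywords")
}

#' Is an organism name blocked from direct matching?
#'
#' @param name organism full name.
#' @param keywords a [blocked_keywords()] object.
#' @return TRUE iff any name keyword occurs, case-insensitively, in `name`.
#' @export
is_blocked_name <- function(name, keywords = blocked_keywords()) {
  low <- tolower(name)
  any(vapply(keywords$name_keywords, grepl, logical(1), x = low,
             fixed = TRUE))
}

#' Is a taxonomic-path element unusable?
#' @inheritParams is_blocked_name
#' @return TRUE iff any path keyword occurs, case-insensitively, in `name`.
#' @export
is_blocked_path_element <- function(name, keywords = blocked_keywords()) {
  low <- tolower(name)
  any(vapply(keywords$path_keywords, grepl, logical(1), x = low,
             fixed = TRUE))
}

#' Capitalization variants of a name, in retry order
#'
#' Variants tried when the exact-case lookup misses: all-lowercase, then
#' first-letter-uppercased with the rest lowered, then each word capitalized.
#' The original form is excluded and duplicates dropped.
#'
#' @param name a taxon or organism name.
#' @return character vector of variants (possibly empty).
#' @export
capitalization_variants <- function(name) {
  lower <- tolower(name)
  sentence <- sub("^(.)", "\\U\\1", lower, perl = TRUE)
  title <- gsub("(^|\\s)(.)", "\\1\\U\\2", lower, perl = TRUE)
  setdiff(unique(c(lower, sentence, title)), name)
}

# lookup with optional capitalization retry; returns id or NA
resolve_with_retry <- function(index, name, try_caps = TRUE) {
  id <- resolve_taxon_id(index, name)
  if (!is.na(id) || !try_caps) return(list(id = id, retried = FALSE))
  for (v in capitalization_variants(name)) {
    id <- resolve_taxon_id(index, v)
    if (!is.na(id)) return(list(id = id, retried = TRUE))
  }
  list(id = NA_integer_, retried = FALSE)
}

#' Climb a taxonomic path to its deepest resolvable taxon
#'
#' Walks the path from its lowest (last) element towards the root, skipping
#' elements containing a path keyword, and returns the first element that
#' resolves in the name index. Each element gets the same capitalization
#' retry as the full-name match.
#'
#' @param path character vector of taxon names, highest rank first.
#' @param index a `name_index`.
#' @param keywords a [blocked_keywords()] object.
#' @param try_caps also try capitalization variants per element.
#' @return list with `taxon_id` (or `NA_integer_` if nothing resolves) and
#'   `depth` (1 = last path element; `NA` when unmapped).
#' @export
search_full_taxa <- function(path, index, keywords = blocked_keywords(),
                             try_caps = TRUE) {
  stopifnot(length(path) >= 1L)
  for (d in seq_along(path)) {
    elem <- path[length(path) - d + 1L]
    if (is_blocked_path_element(elem, keywords)) next
    r <- resolve_with_retry(index, elem, try_caps = try_caps)
    if (!is.na(r$id)) return(list(taxon_id = r$id, depth = d))
  }
  list(taxon_id = NA_integer_, depth = NA_integer_)
}

#' Map one SILVA entry to an NCBI taxon id
#'
#' If the full name is not blocked and resolves in the index, it wins
#' (exact case first, then capitalization variants). A blocked or
#' unresolvable full name falls through to [search_full_taxa()] on the
#' taxonomic path.
#'
#' @param entry a `silva_entry`.
#' @param index a `name_index`.
#' @param keywords a [blocked_keywords()] object.
#' @return list with `taxon_id` (or `NA_integer_`) and `provenance`, one of
#'   `"full-name match"`, `"capitalization retry"`,
#'   `"path match at depth <d>"` or `"unmapped"`.
#' @export
map_entry <- function(entry, index, keywords = blocked_keywords()) {
  full <- entry$full_name
  if (nzchar(full) && !is_blocked_name(full, keywords)) {
    r <- resolve_with_retry(index, full, try_caps = TRUE)
    if (!is.na(r$id)) {
      return(list(taxon_id = r$id,
                  provenance = if (r$retried) "capitalization retry"
                               else "full-name match"))
    }
  }
  s <- search_full_taxa(entry$taxonomic_path, index, keywords, try_caps = TRUE)
  if (!is.na(s$taxon_id)) {
    return(list(taxon_id = s$taxon_id,
                provenance = sprintf("path match at depth %d", s$depth)))
  }
  list(taxon_id = NA_integer_, provenance = "unmapped")
}

#' Build the accession-to-taxon mapping from SILVA entries
#'
#' Runs [map_entry()] over every entry. Duplicate accessions keep the last
#' occurrence (with a warning). Entries that fail to map are excluded from
#' the mapping rows but counted in the summary.
#'
#' @param entries list of `silva_entry` objects.
#' @param index a `name_index`.
#' @param keywords a [blocked_keywords()] object.
#' @return a `mapping_file`: data.frame with columns `accession`, `taxon_id`,
#'   `provenance`, plus a `summary` attribute (counts by provenance and
#'   the unmapped count).
#' @export
build_mapping <- function(entries, index, keywords = blocked_keywords()) {
  accs <- vapply(entries, `[[`, character(1), "accession")
  if (anyDuplicated(accs)) {
    dup <- unique(accs[duplicated(accs)])
    warning(sprintf("duplicate accession(s), last occurrence wins: %s",
                    paste(dup, collapse = ", ")), call. = FALSE)
    keep <- !duplicated(accs, fromLast = TRUE)
    entries <- entries[keep]
    accs <- accs[keep]
  }
  n <- length(entries)
  taxon_id <- integer(n); provenance <- character(n)
  for (i in seq_len(n)) {
    m <- map_entry(entries[[i]], index, keywords)
    taxon_id[i] <- m$taxon_id
    provenance[i] <- m$provenance
  }
  mapped <- !is.na(taxon_id)
  prov_class <- sub(" at depth [0-9]+$", "", provenance)
  summary <- c(table(prov_class[mapped]), unmapped = sum(!mapped),
               total = n)
  structure(data.frame(accession = accs[mapped], taxon_id = taxon_id[mapped],
                       provenance = provenance[mapped],
                       stringsAsFactors = FALSE),
            summary = summary, class = c("mapping_file", "data.frame"))
}

#' Write a mapping file
#'
#' Two tab-separated columns: accession, taxon id. This is the "synonym"
#' file consumed at import time by the accession-lookup step.
#'
#' @param mapping a `mapping_file` (or data.frame with `accession`,
#'   `taxon_id`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mapping_file <- function(mapping, path) {
  writeLines(sprintf("%s\t%d", mapping$accession, mapping$taxon_id), path)
  invisible(path)
}

#' Read a mapping file
#'
#' @param path path to a two-column tab-separated accession/taxon-id file.
#' @return a `mapping_file` data.frame (provenance column filled with
#'   `"file"`).
#' @export
read_mapping_file <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(sub("\r$", "", lines))]
  n <- length(lines)
  accession <- character(n); taxon_id <- integer(n)
  for (i in seq_len(n)) {
    f <- strsplit(sub("\r$", "", lines[i]), "\t", fixed = TRUE)[[1]]
    id <- if (length(f) >= 2L) suppressWarnings(as.integer(f[2])) else NA
    if (length(f) < 2L || is.na(id)) {
      stop(sprintf("mapping file %s: malformed line %d", path, i),
           call. = FALSE)
    }
    accession[i] <- f[1]; taxon_id[i] <- id
  }
  structure(data.frame(accession = accession, taxon_id = taxon_id,
                       provenance = rep("file", n), stringsAsFactors = FALSE),
            class = c("mapping_file", "data.frame"))
}

#' Accession -> taxon id lookup table from a mapping
#' @keywords internal
mapping_lookup <- function(mapping) {
  stats::setNames(mapping$taxon_id, mapping$accession)
}
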