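# ---- profile comparison across samples and classifiers ---------------------

#' Import a genus/abundance CSV profile
#'
#' Reads a headerless two-column CSV (genus name, non-negative integer
#' abundance), as exported by flat genus-level classifiers. Genus names are
#' resolved through the name index with the usual homonym rule; rows whose
#' name does not resolve accumulate in the profile's no-hits bin.
#'
#' @param path path to the CSV file.
#' @param index a `name_index`.
#' @param sample_id label for the profile (default: file base name).
#' @return a `tax_profile`; all mass sits flat on the resolved genus nodes.
#' @export
import_csv_profile <- function(path, index,
                               sample_id = sub("\\.[^.]*$", "", basename(path))) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(sub("\r$", "", lines))]
  counts <- numeric(0)
  no_hits <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(sub("\r$", "", lines[i]), ",", fixed = TRUE)[[1]]
    if (length(f) != 2L) {
      stop(sprintf("CSV profile %s: line %d has %d fields (expected 2)",
                   path, i, length(f)), call. = FALSE)
    }
    ab <- suppressWarnings(as.numeric(trimws(f[2])))
    if (is.na(ab) || ab != round(ab) || ab < 0) {
      stop(sprintf("CSV profile %s: line %d: abundance '%s' is not a non-negative integer",
                   path, i, f[2]), call. = FALSE)
    }
    id <- resolve_taxon_id(index, f[1])
    if (is.na(id)) {
      no_hits <- no_hits + as.integer(ab)
    } else {
      key <- as.character(id)
      counts[key] <- (if (is.na(counts[key])) 0 else counts[[key]]) + ab
    }
  }
  tax_profile(sample_id, counts, no_hits = no_hits)
}

#' Subtree-summarized counts of a profile
#'
#' The summarized value of a node is its own count plus the counts of every
#' node in the subtree below it; the root's summarized value is the total
#' assigned count.
#'
#' @param profile a `tax_profile` whose taxa are all in `tree`.
#' @param tree a `taxonomy_tree`.
#' @return named numeric vector over all tree nodes, taxon id -> subtree
#'   total.
#' @export
summarize_profile <- function(profile, tree) {
  keys <- names(tree$parent)
  out <- stats::setNames(rep(0, length(keys)), keys)
  missing <- setdiff(names(profile$counts), keys)
  if (length(missing)) {
    stop(sprintf("profile taxa absent from tree: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  # every counted node contributes to each of its ancestors (and itself)
  for (key in names(profile$counts)) {
    anc <- as.character(ancestors_of(tree, as.integer(key)))
    out[anc] <- out[anc] + profile$counts[[key]]
  }
  out
}

#' Build a side-by-side comparison table
#'
#' Takes the union of taxa across the profiles, zero-filling absences, and
#' computes both the raw per-node counts and the subtree-summarized values
#' for every sample column.
#'
#' @param profiles non-empty list of `tax_profile` objects.
#' @param tree a `taxonomy_tree`.
#' @return a `comparison_table`: list with `taxa` (character ids, ordered by
#'   total count descending then id), `columns` (sample ids in input order),
#'   `values` and `summarized` matrices (taxa x columns).
#' @export
build_comparison <- function(profiles, tree) {
  stopifnot(length(profiles) >= 1L)
  cols <- vapply(profiles, `[[`, character(1), "sample_id")
  if (anyDuplicated(cols)) {
    cols <- make.unique(cols, sep = "_")
  }
  taxa <- unique(unlist(lapply(profiles, function(p) names(p$counts))))
  if (is.null(taxa)) taxa <- character(0)
  values <- matrix(0, nrow = length(taxa), ncol = length(cols),
                   dimnames = list(taxa, cols))
  summarized <- matrix(0, nrow = length(taxa), ncol = length(cols),
                       dimnames = list(taxa, cols))
  for (j in seq_along(profiles)) {
    p <- profiles[[j]]
    values[names(p$counts), j] <- p$counts
    if (length(taxa)) {
      s <- summarize_profile(p, tree)
      summarized[, j] <- s[taxa]
    }
  }
  if (length(taxa)) {
    ord <- order(-rowSums(values), as.integer(taxa))
    taxa <- taxa[ord]
    values <- values[ord, , drop = FALSE]
    summarized <- summarized[ord, , drop = FALSE]
  }
  structure(list(taxa = taxa, columns = cols, values = values,
                 summarized = summarized), class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("<comparison_table> %d taxa x %d samples (%s)\n",
              length(x$taxa), length(x$columns),
              paste(x$columns, collapse = ", ")))
  invisible(x)
}

#' Write a comparison table as TSV
#'
#' Columns: taxon_id, name, rank, then one raw-count and one summarized
#' column per sample.
#'
#' @param comparison a `comparison_table`.
#' @param path output path.
#' @param tree optional `taxonomy_tree` for the rank column.
#' @param names_df optional names data.frame for the name column.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path, tree = NULL, names_df = NULL) {
  header <- paste(c("taxon_id", "name", "rank",
                    paste0(comparison$columns, ".count"),
                    paste0(comparison$columns, ".summarized")),
                  collapse = "\t")
  sci <- if (!is.null(names_df)) {
    s <- names_df[names_df$name_class == "scientific name", ]
    stats::setNames(s$name, as.character(s$taxon_id))
  } else NULL
  rows <- vapply(seq_along(comparison$taxa), function(i) {
    id <- comparison$taxa[i]
    nm <- if (!is.null(sci) && !is.na(sci[id])) sci[[id]] else ""
    rk <- if (!is.null(tree) && !is.na(tree$rank[id])) tree$rank[[id]] else ""
    paste(c(id, nm, rk, comparison$values[i, ], comparison$summarized[i, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
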