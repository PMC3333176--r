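# ---- SILVA ARB "NDS field export" parsing ---------------------------------
#
# One record per line: accession, semicolon-separated taxonomic path, full
# organism name. ARB's NDS export writes tab-separated columns by default;
# the delimiter is configurable for other export settings.

#' Construct a SILVA export entry
#'
#' @param accession non-empty accession string.
#' @param taxonomic_path character vector of taxon names, highest rank first.
#' @param full_name organism full name (may be empty).
#' @return a `silva_entry` object.
#' @export
silva_entry <- function(accession, taxonomic_path, full_name = "") {
  accession <- trimws(accession)
  taxonomic_path <- trimws(taxonomic_path)
  # drop trailing empties (a path ending "…; Genus;" exports an empty cell)
  while (length(taxonomic_path) && !nzchar(taxonomic_path[length(taxonomic_path)])) {
    taxonomic_path <- taxonomic_path[-length(taxonomic_path)]
  }
  if (!nzchar(accession)) stop("empty accession", call. = FALSE)
  if (!length(taxonomic_path) || any(!nzchar(taxonomic_path))) {
    stop(sprintf("entry %s: empty taxonomic path element", accession),
         call. = FALSE)
  }
  structure(list(accession = accession, taxonomic_path = taxonomic_path,
                 full_name = trimws(full_name)), class = "silva_entry")
}

#' @export
print.silva_entry <- function(x, ...) {
  cat(sprintf("<silva_entry> %s  [%s]  '%s'\n", x$accession,
              paste(x$taxonomic_path, collapse = "; "), x$full_name))
  invisible(x)
}

#' Parse a SILVA NDS field export file
#'
#' Expects one record per line with three delimited columns: accession,
#' taxonomic path (elements separated by `";"`, trimmed, trailing empties
#' dropped) and organism full name. Path order is preserved exactly.
#'
#' @param path path to the export file.
#' @param delim column delimiter, default tab.
#' @return list of `silva_entry` objects.
#' @export
parse_silva_export <- function(path, delim = "\t") {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(sub("\r$", "", lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(sub("\r$", "", lines[i]), delim, fixed = TRUE)[[1]]
    if (length(f) < 2L) {
      stop(sprintf("SILVA export %s: malformed line %d (need accession and path)",
                   path, i), call. = FALSE)
    }
    acc <- trimws(f[1])
    path_elems <- strsplit(f[2], ";", fixed = TRUE)[[1]]
    full <- if (length(f) >= 3L) f[3] else ""
    out[[i]] <- tryCatch(
      silva_entry(acc, path_elems, full),
      error = function(e) stop(sprintf("SILVA export %s: line %d: %s",
                                       path, i, conditionMessage(e)),
                               call. = FALSE))
  }
  out
}

#' Write SILVA entries in NDS-export dialect
#'
#' Inverse of [parse_silva_export()]; used by the fixture generators and for
#' round-trip testing.
#'
#' @param entries list of `silva_entry` objects.
#' @param path output path.
#' @param delim column delimiter, default tab.
#' @return `path`, invisibly.
#' @export
write_silva_export <- function(entries, path, delim = "\t") {
  lines <- vapply(entries, function(e) {
    paste(e$accession, paste(e$taxonomic_path, collapse = "; "), e$full_name,
          sep = delim)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
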