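# ---- NCBI taxonomy dump parsing -------------------------------------------
#
# The taxdump flat files delimit fields with "\t|\t" and terminate each line
# with "\t|".  names.dmp carries (taxon_id, name_txt, unique name, name
# class); nodes.dmp carries (taxon_id, parent_id, rank, ...).

NAME_CLASSES <- c("scientific name", "synonym", "equivalent name",
                  "misspelling")

#' Split one taxdump line into its fields
#'
#' Strips the trailing `"\t|"` terminator and splits on the `"\t|\t"` field
#' separator. Trailing `\r` (CRLF files) is tolerated.
#' @param line character scalar, one raw dump line.
#' @return character vector of fields.
#' @keywords internal
split_dmp_line <- function(line) {
  line <- sub("\r$", "", line)
  line <- sub("\t\\|$", "", line)
  strsplit(line, "\t|\t", fixed = TRUE)[[1]]
}

#' Parse an NCBI names.dmp file
#'
#' Reads the pipe-and-tab delimited names dump and returns one row per name
#' record. The name class is taken verbatim from the fourth field; classes
#' other than scientific name, synonym, equivalent name or misspelling are
#' mapped to `"other"`.
#'
#' @param path path to a names.dmp-dialect file.
#' @return data.frame with columns `taxon_id` (integer), `name` (character,
#'   whitespace-trimmed) and `name_class` (character).
#' @examples
#' f <- tempfile()
#' writeLines("336503\t|\tHomalopoma granuliferum\t|\t\t|\tscientific name\t|", f)
#' parse_names_dump(f)
#' @export
parse_names_dump <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(sub("\r$", "", lines))]
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(taxon_id = integer(), name = character(),
                      name_class = character(), stringsAsFactors = FALSE))
  }
  taxon_id <- integer(n)
  name <- character(n)
  name_class <- character(n)
  for (i in seq_len(n)) {
    f <- split_dmp_line(lines[i])
    if (length(f) < 4L) {
      stop(sprintf("names dump %s: malformed line %d (expected 4 fields, got %d)",
                   path, i, length(f)), call. = FALSE)
    }
    id <- suppressWarnings(as.integer(f[1]))
    if (is.na(id) || id <= 0L) {
      stop(sprintf("names dump %s: malformed line %d (bad taxon id '%s')",
                   path, i, f[1]), call. = FALSE)
    }
    nm <- trimws(f[2])
    if (!nzchar(nm)) {
      stop(sprintf("names dump %s: malformed line %d (empty name)", path, i),
           call. = FALSE)
    }
    taxon_id[i] <- id
    name[i] <- nm
    cls <- trimws(f[4])
    name_class[i] <- if (cls %in% NAME_CLASSES) cls else "other"
  }
  data.frame(taxon_id = taxon_id, name = name, name_class = name_class,
             stringsAsFactors = FALSE)
}

#' Parse an NCBI nodes.dmp file into a taxonomy tree
#'
#' Fields used are taxon id, parent id and rank. The resulting tree must be
#' rooted (exactly one node whose parent is itself) and every parent id must
#' itself be a node; violations are errors.
#'
#' @param path path to a nodes.dmp-dialect file.
#' @return a `taxonomy_tree`: list with integer vector `parent` and character
#'   vector `rank`, both named by taxon id, plus `root_id`.
#' @export
parse_nodes_dump <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(sub("\r$", "", lines))]
  n <- length(lines)
  ids <- integer(n); parents <- integer(n); ranks <- character(n)
  for (i in seq_len(n)) {
    f <- split_dmp_line(lines[i])
    if (length(f) < 3L) {
      stop(sprintf("nodes dump %s: malformed line %d (expected >=3 fields, got %d)",
                   path, i, length(f)), call. = FALSE)
    }
    id <- suppressWarnings(as.integer(f[1]))
    pid <- suppressWarnings(as.integer(f[2]))
    if (is.na(id) || is.na(pid)) {
      stop(sprintf("nodes dump %s: malformed line %d (non-integer ids)", path, i),
           call. = FALSE)
    }
    ids[i] <- id; parents[i] <- pid; ranks[i] <- trimws(f[3])
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("nodes dump %s: duplicate taxon ids: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  taxonomy_tree(ids, parents, ranks)
}

#' Construct a taxonomy tree from parallel id/parent/rank vectors
#'
#' @param ids integer taxon ids.
#' @param parents integer parent ids, parallel to `ids`.
#' @param ranks character ranks, parallel to `ids`.
#' @return a `taxonomy_tree` object.
#' @export
taxonomy_tree <- function(ids, parents, ranks) {
  ids <- as.integer(ids); parents <- as.integer(parents)
  orphans <- setdiff(parents, ids)
  if (length(orphans)) {
    stop(sprintf("orphan parent ids not present as nodes: %s",
                 paste(sort(orphans), collapse = ", ")), call. = FALSE)
  }
  roots <- ids[ids == parents]
  if (length(roots) != 1L) {
    stop(sprintf("tree must have exactly one self-parenting root, found %d",
                 length(roots)), call. = FALSE)
  }
  parent <- stats::setNames(parents, as.character(ids))
  rank <- stats::setNames(as.character(ranks), as.character(ids))
  tree <- structure(list(parent = parent, rank = rank, root_id = roots),
                    class = "taxonomy_tree")
  # cycle check: every node must reach the root
  d <- node_depths(tree)
  if (anyNA(d)) {
    stop(sprintf("cycle detected: nodes not reaching root: %s",
                 paste(names(d)[is.na(d)], collapse = ", ")), call. = FALSE)
  }
  tree
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("<taxonomy_tree> %d nodes, root %d, ranks: %s\n",
              length(x$parent), x$root_id,
              paste(utils::head(sort(unique(unname(x$rank))), 8), collapse = ", ")))
  invisible(x)
}

#' Depth of every node (root = 0); NA marks nodes trapped in a cycle
#' @keywords internal
node_depths <- function(tree) {
  n <- length(tree$parent)
  depth <- stats::setNames(rep(NA_integer_, n), names(tree$parent))
  depth[as.character(tree$root_id)] <- 0L
  for (nm in names(tree$parent)) {
    if (!is.na(depth[[nm]])) next
    chain <- character(0)
    cur <- nm
    while (is.na(depth[[cur]]) && !(cur %in% chain)) {
      chain <- c(chain, cur)
      cur <- as.character(tree$parent[[cur]])
    }
    if (!is.na(depth[[cur]])) {
      base <- depth[[cur]]
      for (k in rev(seq_along(chain))) {
        depth[chain[k]] <- base + (length(chain) - k + 1L)
      }
    }
  }
  depth
}

#' Path from a taxon up to the root, inclusive
#'
#' @param tree a `taxonomy_tree`.
#' @param id taxon id present in the tree.
#' @return integer vector of taxon ids, `id` first, root last.
#' @export
ancestors_of <- function(tree, id) {
  key <- as.character(id)
  if (is.na(tree$parent[key])) {
    stop(sprintf("taxon id %s not in tree", id), call. = FALSE)
  }
  path <- integer(0)
  cur <- as.integer(id)
  repeat {
    path <- c(path, cur)
    nxt <- tree$parent[[as.character(cur)]]
    if (nxt == cur) break
    cur <- nxt
  }
  path
}

#' Lowest common ancestor of a set of taxa
#'
#' Returns the deepest node that lies on the root path of every input taxon
#' (ancestor-or-self of each). Order-independent; `lca(tree, x)` is `x`.
#'
#' @param tree a `taxonomy_tree`.
#' @param ids non-empty vector of taxon ids, all present in the tree.
#' @return single taxon id.
#' @export
lca <- function(tree, ids) {
  ids <- unique(as.integer(ids))
  if (length(ids) == 0L) stop("lca needs at least one taxon id", call. = FALSE)
  missing <- ids[is.na(tree$parent[as.character(ids)])]
  if (length(missing)) {
    stop(sprintf("taxon id(s) not in tree: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  path <- ancestors_of(tree, ids[1])
  if (length(ids) == 1L) return(ids[1])
  for (id in ids[-1]) {
    anc <- ancestors_of(tree, id)
    path <- path[path %in% anc]  # keeps order: deepest first
  }
  path[1]
}

# ---- name index -----------------------------------------------------------

#' Normalize a taxon name for indexing
#'
#' Strips outer whitespace and collapses internal whitespace runs to a single
#' space. Case is preserved: the first matching attempt is exact-case, and
#' capitalization variants are generated separately by the mapping step.
#'
#' @param name character vector.
#' @return normalized character vector. Idempotent.
#' @export
normalize_name <- function(name) {
  gsub("[[:space:]]+", " ", trimws(name))
}

#' Build a hash map from taxon names to taxon ids
#'
#' Indexes every name record (scientific names, synonyms, equivalent names,
#' misspellings) under its normalized form. A name borne by several taxa
#' (a homonym) keeps all of its ids; within each entry, scientific-name
#' records are listed before other classes, then by ascending taxon id.
#'
#' @param records data.frame as returned by [parse_names_dump()].
#' @return a `name_index` object.
#' @export
build_name_index <- function(records) {
  env <- new.env(parent = emptyenv(), hash = TRUE,
                 size = max(16L, nrow(records)))
  if (nrow(records)) {
    key <- normalize_name(records$name)
    sci_first <- ifelse(records$name_class == "scientific name", 0L, 1L)
    ord <- order(key, sci_first, records$taxon_id)
    key <- key[ord]
    ids <- records$taxon_id[ord]
    cls <- records$name_class[ord]
    grp <- split(seq_along(key), key)
    for (k in names(grp)) {
      idx <- grp[[k]]
      keep <- !duplicated(paste(ids[idx], cls[idx]))
      assign(k, data.frame(taxon_id = ids[idx][keep],
                           name_class = cls[idx][keep],
                           stringsAsFactors = FALSE),
             envir = env)
    }
  }
  structure(list(entries = env), class = "name_index")
}

#' Look up a name in the index
#'
#' @param index a `name_index`.
#' @param name a single taxon name (normalized internally).
#' @return data.frame of `(taxon_id, name_class)` matches, scientific-name
#'   entries first; zero rows if the name is absent.
#' @export
lookup_name <- function(index, name) {
  key <- normalize_name(name)
  if (nzchar(key) && exists(key, envir = index$entries, inherits = FALSE)) {
    get(key, envir = index$entries, inherits = FALSE)
  } else {
    data.frame(taxon_id = integer(), name_class = character(),
               stringsAsFactors = FALSE)
  }
}

#' Resolve a name to a single taxon id
#'
#' Homonym rule: prefer the first scientific-name entry; among equally ranked
#' candidates take the numerically smallest taxon id and warn.
#'
#' @param index a `name_index`.
#' @param name a single taxon name.
#' @return taxon id, or `NA_integer_` if the name is absent.
#' @export
resolve_taxon_id <- function(index, name) {
  hits <- lookup_name(index, name)
  if (nrow(hits) == 0L) return(NA_integer_)
  sci <- hits[hits$name_class == "scientific name", , drop = FALSE]
  pool <- if (nrow(sci)) sci else hits
  if (length(unique(pool$taxon_id)) > 1L) {
    warning(sprintf("name '%s' is ambiguous (ids %s); taking smallest id",
                    name, paste(unique(pool$taxon_id), collapse = ", ")),
            call. = FALSE)
  }
  min(pool$taxon_id)
}

#' All taxon ids present in a name index
#' @param index a `name_index`.
#' @return integer vector of taxon ids.
#' @export
index_taxon_ids <- function(index) {
  keys <- ls(envir = index$entries, all.names = TRUE)
  if (!length(keys)) return(integer(0))
  sort(unique(unlist(lapply(keys, function(k)
    get(k, envir = index$entries, inherits = FALSE)$taxon_id))))
}

#' Write taxonomy records back to names.dmp dialect
#' @param records data.frame with taxon_id, name, name_class.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_names_dump <- function(records, path) {
  lines <- sprintf("%d\t|\t%s\t|\t\t|\t%s\t|",
                   records$taxon_id, records$name, records$name_class)
  writeLines(lines, path)
  invisible(path)
}

#' Write a taxonomy tree to nodes.dmp dialect
#' @param tree a `taxonomy_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nodes_dump <- function(tree, path) {
  ids <- names(tree$parent)
  lines <- sprintf("%s\t|\t%d\t|\t%s\t|", ids, unname(tree$parent),
                   unname(tree$rank))
  writeLines(lines, path)
  invisible(path)
}
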