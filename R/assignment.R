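# ---- read assignment: BLAST tabular -> taxonomic profile -------------------

#' Assignment parameters
#'
#' The canonical thresholds for a conservative 16S assignment: hits scoring
#' below `min_score` bits are dropped; surviving hits must lie within
#' `top_percent` percent of the best surviving bit score; taxa attracting
#' fewer than `min_support` reads have their reads pushed up to ancestors.
#'
#' @param min_score minimum bit score for a hit to count (default 120).
#' @param top_percent width, in percent of the best retained bit score, of
#'   the band of hits entering the LCA (default 10).
#' @param min_support minimum number of reads a taxon must attract
#'   (default 5).
#' @return an `assignment_params` object.
#' @export
assignment_params <- function(min_score = 120, top_percent = 10,
                              min_support = 5L) {
  stopifnot(min_score >= 0, top_percent > 0, top_percent <= 100,
            min_support >= 1)
  structure(list(min_score = min_score, top_percent = top_percent,
                 min_support = as.integer(min_support)),
            class = "assignment_params")
}

#' Parse 12-column BLAST tabular output
#'
#' The standard tabular dialect: query, subject, percent identity, alignment
#' length, mismatches, gap opens, qstart, qend, sstart, send, e-value, bit
#' score. Hits are grouped by query with input order preserved.
#'
#' @param path path to the tabular file.
#' @return named list: query id -> data.frame of hits with columns
#'   `subject_accession`, `percent_identity`, `alignment_length`, `evalue`,
#'   `bit_score`.
#' @export
parse_blast_tabular <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(sub("\r$", "", lines))]
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) return(structure(list(), names = character(0)))
  parts <- strsplit(sub("\r$", "", lines), "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad)) {
    stop(sprintf("BLAST tabular %s: line %d has %d columns (expected 12)",
                 path, bad[1], lengths(parts)[bad[1]]), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  hits <- data.frame(query_id = m[, 1], subject_accession = m[, 2],
                     percent_identity = as.numeric(m[, 3]),
                     alignment_length = as.integer(m[, 4]),
                     evalue = as.numeric(m[, 11]),
                     bit_score = as.numeric(m[, 12]),
                     stringsAsFactors = FALSE)
  split(hits[-1], factor(hits$query_id, levels = unique(hits$query_id)))
}

#' Filter hits by Min Score and Top Percent
#'
#' Drops hits with `bit_score < min_score`; among the survivors keeps those
#' with `bit_score >= (1 - top_percent/100) * best`, where `best` is the top
#' surviving bit score.
#'
#' @param hits data.frame of hits with a `bit_score` column.
#' @param params an [assignment_params()] object.
#' @return the retained subset of `hits` (possibly zero rows).
#' @export
filter_hits <- function(hits, params = assignment_params()) {
  keep <- hits$bit_score >= params$min_score
  surv <- hits[keep, , drop = FALSE]
  if (nrow(surv) == 0L) return(surv)
  cutoff <- (1 - params$top_percent / 100) * max(surv$bit_score)
  surv[surv$bit_score >= cutoff, , drop = FALSE]
}

#' Assign one read to a taxon
#'
#' Identical (query, accession) pairs are collapsed to their best bit score
#' first (multiple HSPs must not double-count). The retained hits' accessions
#' are resolved through the mapping file and the read is assigned to the LCA
#' of the resolved taxa.
#'
#' @param read_id read identifier.
#' @param hits data.frame of this read's hits (may have zero rows).
#' @param mapping a `mapping_file`.
#' @param tree a `taxonomy_tree`.
#' @param params an [assignment_params()] object.
#' @return list with `read_id`, `status` (one of `"assigned"`, `"no-hits"`,
#'   `"unassigned-low-score"`, `"unmapped-accession"`) and `taxon_id`
#'   (`NA` unless assigned).
#' @export
assign_read <- function(read_id, hits, mapping, tree,
                        params = assignment_params()) {
  if (is.null(hits) || nrow(hits) == 0L) {
    return(list(read_id = read_id, status = "no-hits", taxon_id = NA_integer_))
  }
  # best HSP per accession
  ord <- order(-hits$bit_score)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$subject_accession), , drop = FALSE]
  retained <- filter_hits(hits, params)
  if (nrow(retained) == 0L) {
    return(list(read_id = read_id, status = "unassigned-low-score",
                taxon_id = NA_integer_))
  }
  ids <- mapping_lookup(mapping)[retained$subject_accession]
  if (all(is.na(ids))) {
    return(list(read_id = read_id, status = "unmapped-accession",
                taxon_id = NA_integer_))
  }
  known <- ids[!is.na(ids)]
  absent <- is.na(tree$parent[as.character(known)])
  if (any(absent)) {
    stop(sprintf("read %s: accession %s maps to taxon %d absent from tree",
                 read_id, retained$subject_accession[!is.na(ids)][absent][1],
                 known[absent][1]), call. = FALSE)
  }
  list(read_id = read_id, status = "assigned",
       taxon_id = lca(tree, unique(known)))
}

# ---- taxonomic profile -----------------------------------------------------

#' Construct a taxonomic profile
#'
#' @param sample_id sample label.
#' @param counts named numeric vector, taxon id (as name) -> read count.
#' @param no_hits reads with no hits at all.
#' @param unassigned reads whose hits all failed the Min Score threshold.
#' @param unmapped reads whose retained hits all miss the mapping file.
#' @return a `tax_profile` object.
#' @export
tax_profile <- function(sample_id, counts = numeric(0), no_hits = 0L,
                        unassigned = 0L, unmapped = 0L) {
  counts <- counts[counts > 0]
  stopifnot(all(counts >= 0), no_hits >= 0, unassigned >= 0, unmapped >= 0)
  structure(list(sample_id = sample_id, counts = counts,
                 no_hits = as.integer(no_hits),
                 unassigned = as.integer(unassigned),
                 unmapped = as.integer(unmapped)),
            class = "tax_profile")
}

#' Total number of reads in a profile (assigned + special bins)
#' @param profile a `tax_profile`.
#' @return integer total.
#' @export
profile_total <- function(profile) {
  sum(profile$counts) + profile$no_hits + profile$unassigned + profile$unmapped
}

#' @export
print.tax_profile <- function(x, ...) {
  cat(sprintf("<tax_profile> sample '%s': %d taxa, %d assigned reads; no-hits %d, unassigned %d, unmapped %d\n",
              x$sample_id, length(x$counts), sum(x$counts), x$no_hits,
              x$unassigned, x$unmapped))
  invisible(x)
}

#' Apply the Min Support threshold by pushing reads up the tree
#'
#' Nodes are processed deepest-first in a single pass; a non-root node whose
#' count (including reads already pushed into it) is positive but below
#' `min_support` has all its reads moved to its parent. The root keeps
#' whatever reaches it. Total reads are conserved.
#'
#' @param profile a `tax_profile` of direct assignment counts.
#' @param tree a `taxonomy_tree`.
#' @param params an [assignment_params()] object.
#' @return a `tax_profile` in which every taxon with a positive count has at
#'   least `min_support` reads, except possibly the root.
#' @export
apply_min_support <- function(profile, tree, params = assignment_params()) {
  ms <- params$min_support
  if (ms <= 1L || length(profile$counts) == 0L) return(profile)
  counts <- profile$counts
  missing <- names(counts)[is.na(tree$parent[names(counts)])]
  if (length(missing)) {
    stop(sprintf("profile taxa absent from tree: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  depth <- node_depths(tree)
  # all nodes that could ever receive pushed-up reads: counted nodes plus
  # their ancestors; deepest first so pushes arrive before a node is checked
  active <- unique(unlist(lapply(as.integer(names(counts)),
                                 function(id) ancestors_of(tree, id))))
  active <- as.character(active[order(-depth[as.character(active)])])
  full <- stats::setNames(rep(0, length(active)), active)
  full[names(counts)] <- counts
  root_key <- as.character(tree$root_id)
  for (key in active) {
    cnt <- full[[key]]
    if (key != root_key && cnt > 0 && cnt < ms) {
      parent_key <- as.character(tree$parent[[key]])
      full[parent_key] <- full[[parent_key]] + cnt
      full[key] <- 0
    }
  }
  counts <- full
  tax_profile(profile$sample_id, counts, profile$no_hits,
              profile$unassigned, profile$unmapped)
}

#' Collapse a profile at a named rank
#'
#' Each taxon's count is accumulated onto its nearest ancestor-or-self whose
#' rank equals `rank`; taxa with no such ancestor keep their own bin. Totals
#' are conserved.
#'
#' @param profile a `tax_profile`.
#' @param tree a `taxonomy_tree`.
#' @param rank a rank name occurring in the tree (e.g. `"genus"`).
#' @return collapsed `tax_profile`.
#' @export
collapse_at_rank <- function(profile, tree, rank) {
  if (!rank %in% tree$rank) {
    stop(sprintf("rank '%s' does not occur in the tree", rank), call. = FALSE)
  }
  out <- numeric(0)
  for (key in names(profile$counts)) {
    target <- key
    for (anc in ancestors_of(tree, as.integer(key))) {
      if (tree$rank[[as.character(anc)]] == rank) {
        target <- as.character(anc)
        break
      }
    }
    out[target] <- (if (is.na(out[target])) 0 else out[[target]]) +
      profile$counts[[key]]
  }
  tax_profile(profile$sample_id, out, profile$no_hits, profile$unassigned,
              profile$unmapped)
}

#' Run the full assignment pipeline on files
#'
#' Parses the BLAST tabular file, the mapping file and the taxonomy dumps,
#' assigns every read (accession lookup, Min Score / Top Percent filtering,
#' LCA), tallies a profile and applies Min Support push-up.
#'
#' @param blast_path BLAST 12-column tabular file.
#' @param mapping_path two-column accession/taxon-id mapping file.
#' @param names_path names.dmp-dialect file (kept for interface symmetry;
#'   names are not needed for assignment itself).
#' @param nodes_path nodes.dmp-dialect file.
#' @param params an [assignment_params()] object.
#' @param sample_id label for the resulting profile.
#' @param read_ids optional character vector of all sequenced read ids;
#'   reads absent from the BLAST file are then counted in the no-hits bin.
#' @return a `tax_profile`, with attribute `assignments` (data.frame of
#'   per-read status and taxon).
#' @export
run_assignment <- function(blast_path, mapping_path, names_path = NULL,
                           nodes_path, params = assignment_params(),
                           sample_id = "sample", read_ids = NULL) {
  by_query <- parse_blast_tabular(blast_path)
  mapping <- read_mapping_file(mapping_path)
  tree <- parse_nodes_dump(nodes_path)
  qids <- names(by_query)
  res <- lapply(qids, function(q)
    assign_read(q, by_query[[q]], mapping, tree, params))
  status <- vapply(res, `[[`, character(1), "status")
  taxon <- vapply(res, `[[`, integer(1), "taxon_id")
  n_no_hits <- 0L
  if (!is.null(read_ids)) {
    extra <- setdiff(read_ids, qids)
    n_no_hits <- length(extra)
    if (length(extra)) {
      status <- c(status, rep("no-hits", length(extra)))
      taxon <- c(taxon, rep(NA_integer_, length(extra)))
      qids <- c(qids, extra)
    }
  }
  assigned <- taxon[status == "assigned"]
  counts <- numeric(0)
  if (length(assigned)) {
    tab <- table(assigned)
    counts <- stats::setNames(as.numeric(tab), names(tab))
  }
  profile <- tax_profile(sample_id, counts,
                         no_hits = n_no_hits,
                         unassigned = sum(status == "unassigned-low-score"),
                         unmapped = sum(status == "unmapped-accession"))
  profile <- apply_min_support(profile, tree, params)
  attr(profile, "assignments") <- data.frame(read_id = qids, status = status,
                                             taxon_id = taxon,
                                             stringsAsFactors = FALSE)
  profile
}

#' Write a profile as tab-separated text
#'
#' Columns: taxon_id, taxon_name, rank, count; sorted by count descending
#' then taxon id; special bins appended as `NoHits`, `Unassigned`,
#' `UnmappedAccession` rows with taxon_id `-1`.
#'
#' @param profile a `tax_profile`.
#' @param path output path.
#' @param tree optional `taxonomy_tree` for the rank column.
#' @param names_df optional data.frame from [parse_names_dump()] for the
#'   name column (scientific names used).
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, tree = NULL, names_df = NULL) {
  ids <- names(profile$counts)
  ord <- order(-profile$counts, as.integer(ids))
  ids <- ids[ord]
  name_of <- function(id) {
    if (is.null(names_df)) return("")
    sci <- names_df$name[names_df$taxon_id == as.integer(id) &
                           names_df$name_class == "scientific name"]
    if (length(sci)) sci[1] else ""
  }
  rank_of <- function(id) {
    if (is.null(tree)) return("")
    r <- tree$rank[id]
    if (is.na(r)) "" else r
  }
  lines <- c("taxon_id\ttaxon_name\trank\tcount",
             vapply(ids, function(id)
               sprintf("%s\t%s\t%s\t%d", id, name_of(id), rank_of(id),
                       as.integer(profile$counts[[id]])), character(1)),
             sprintf("-1\tNoHits\t\t%d", profile$no_hits),
             sprintf("-1\tUnassigned\t\t%d", profile$unassigned),
             sprintf("-1\tUnmappedAccession\t\t%d", profile$unmapped))
  writeLines(lines, path)
  invisible(path)
}
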