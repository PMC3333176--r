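# ---- synthetic fixture generators ------------------------------------------
#
# Everything the pipeline consumes (taxonomy dumps, SILVA exports, BLAST
# tables) can be generated synthetically with a recorded ground-truth
# manifest, so each stage is testable without any database download. Each
# generator draws from its own pseudo-random stream derived from
# (seed, generator name), so adding a generator never perturbs the others.

RANK_LADDER <- c("superkingdom", "phylum", "class", "order", "family",
                 "genus", "species")

#' Fixture generation parameters
#'
#' @param n_taxa total taxonomy nodes including the root (>= 2).
#' @param n_accessions number of SILVA accessions to simulate.
#' @param n_reads number of simulated reads in the BLAST table.
#' @param blocked_frac fraction of accessions whose full name carries a
#'   blocked keyword ("uncultured ...") so mapping must climb the path.
#' @param mangled_frac fraction of accessions whose full name is
#'   case-mangled so mapping must use the capitalization retry.
#' @param unmappable_frac fraction of accessions whose name and path resolve
#'   nowhere (left out of the mapping file).
#' @param synonym_frac fraction of taxa given an extra synonym/equivalent
#'   name/misspelling record in names.dmp.
#' @param homonym_frac fraction of taxa whose name is additionally recorded
#'   as a synonym of another taxon (homonym lists in the index).
#' @param lowscore_frac fraction of reads whose hits all score below the
#'   Min Score default.
#' @param decoy_frac fraction of assignable reads receiving extra lower-
#'   scoring decoy hits to other accessions.
#' @param score_range bit-score bounds for true hits.
#' @param lowscore_range bit-score bounds for low-score reads.
#' @return a `fixture_params` object.
#' @export
fixture_params <- function(n_taxa = 200L, n_accessions = 500L,
                           n_reads = 2000L, blocked_frac = 0.2,
                           mangled_frac = 0.1, unmappable_frac = 0.05,
                           synonym_frac = 0.2, homonym_frac = 0.05,
                           lowscore_frac = 0.1, decoy_frac = 0.3,
                           score_range = c(150, 250),
                           lowscore_range = c(40, 119)) {
  stopifnot(n_taxa >= 2, n_accessions >= 1, n_reads >= 0,
            blocked_frac >= 0, blocked_frac <= 1,
            mangled_frac >= 0, mangled_frac <= 1,
            unmappable_frac >= 0, unmappable_frac <= 1,
            blocked_frac + mangled_frac + unmappable_frac <= 1,
            lowscore_frac >= 0, lowscore_frac <= 1,
            decoy_frac >= 0, decoy_frac <= 1,
            score_range[1] <= score_range[2],
            lowscore_range[1] <= lowscore_range[2])
  structure(list(n_taxa = as.integer(n_taxa),
                 n_accessions = as.integer(n_accessions),
                 n_reads = as.integer(n_reads),
                 blocked_frac = blocked_frac, mangled_frac = mangled_frac,
                 unmappable_frac = unmappable_frac,
                 synonym_frac = synonym_frac, homonym_frac = homonym_frac,
                 lowscore_frac = lowscore_frac, decoy_frac = decoy_frac,
                 score_range = score_range, lowscore_range = lowscore_range),
            class = "fixture_params")
}

# per-generator pseudo-random stream; keeps streams independent
fixture_seed <- function(seed, generator) {
  ((as.numeric(seed) %% 100000) * 7919 +
     sum(utf8ToInt(generator)) * 131) %% 2147483647
}

# Latin-ish unique taxon names
make_name_pool <- function(n, used = character(0), capital = TRUE) {
  syll <- c("ba", "co", "di", "fu", "ga", "lo", "mi", "no", "pe", "ra",
            "si", "tu", "ve", "xa", "zo", "cil", "ther", "vib", "spir",
            "bact")
  out <- character(0)
  while (length(out) < n) {
    k <- sample(2:4, 1)
    nm <- paste(sample(syll, k, replace = TRUE), collapse = "")
    if (capital) nm <- sub("^(.)", "\\U\\1", nm, perl = TRUE)
    if (!(nm %in% used) && !(nm %in% out)) out <- c(out, nm)
  }
  out
}

#' Generate a synthetic taxonomy (names.dmp + nodes.dmp + manifest)
#'
#' Builds a rooted tree over the canonical rank ladder (superkingdom ...
#' genus, species), writes it in taxdump dialect, and records the true
#' topology and names in the manifest. A share of taxa receive extra
#' synonym/equivalent-name/misspelling records; with enough nodes, one
#' "environmental samples" node is placed under a genus to exercise the
#' path-keyword skip.
#'
#' @param dir output directory (created if needed).
#' @param params a [fixture_params()] object.
#' @param seed integer seed; identical seeds yield byte-identical files.
#' @return a `fixture_manifest`: list with `taxa` (data.frame taxon_id,
#'   parent_id, rank, name), `name_records` (all names.dmp rows),
#'   `names_path`, `nodes_path`, `env_node` (id or NA), `seed`, `params`.
#' @export
generate_taxonomy <- function(dir, params = fixture_params(), seed = 42L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(fixture_seed(seed, "taxonomy"))
  n <- params$n_taxa
  want_env <- n >= 10L
  n_named <- n - 1L - as.integer(want_env)  # minus root, minus env node

  ids <- integer(0); parents <- integer(0); ranks <- character(0)
  names_vec <- character(0)
  add_node <- function(id, parent, rank, name) {
    ids <<- c(ids, id); parents <<- c(parents, parent)
    ranks <<- c(ranks, rank); names_vec <<- c(names_vec, name)
  }
  add_node(1L, 1L, "no rank", "root")
  by_level <- list(`0` = 1L)  # level -> ids (root at level 0)
  used <- "root"
  genus_name_of <- stats::setNames(character(0), character(0))

  next_id <- 2L
  for (i in seq_len(n_named)) {
    max_level <- min(i, length(RANK_LADDER))
    # first nodes build a chain so every ladder level is populated
    level <- if (i <= length(RANK_LADDER)) i else sample(seq_len(max_level), 1,
      prob = seq_len(max_level))  # weight toward deeper levels
    parent <- if (level == 1L) 1L else {
      pool <- by_level[[as.character(level - 1L)]]
      pool[sample.int(length(pool), 1)]
    }
    rank <- RANK_LADDER[level]
    if (rank == "species") {
      genus <- genus_name_of[[as.character(parent)]]
      repeat {
        nm <- paste(genus, tolower(make_name_pool(1)))
        if (!(nm %in% used)) break
      }
    } else {
      nm <- make_name_pool(1, used)
    }
    used <- c(used, nm)
    add_node(next_id, parent, rank, nm)
    if (rank == "genus") genus_name_of[as.character(next_id)] <- nm
    by_level[[as.character(level)]] <- c(by_level[[as.character(level)]],
                                         next_id)
    next_id <- next_id + 1L
  }

  env_node <- NA_integer_
  if (want_env) {
    genus_pool <- ids[ranks == "genus"]
    parent <- genus_pool[sample.int(length(genus_pool), 1)]
    env_node <- next_id
    add_node(env_node, parent, "no rank", "environmental samples")
  }

  taxa <- data.frame(taxon_id = ids, parent_id = parents, rank = ranks,
                     name = names_vec, stringsAsFactors = FALSE)

  # names.dmp records: scientific for all, plus extra name classes
  rec <- data.frame(taxon_id = ids, name = names_vec,
                    name_class = "scientific name", stringsAsFactors = FALSE)
  non_root <- which(ids != 1L)
  n_syn <- round(params$synonym_frac * length(non_root))
  if (n_syn > 0) {
    pick <- sample(non_root, n_syn)
    alt <- make_name_pool(n_syn, used)
    used <- c(used, alt)
    cls <- sample(c("synonym", "equivalent name", "misspelling"), n_syn,
                  replace = TRUE)
    rec <- rbind(rec, data.frame(taxon_id = ids[pick], name = alt,
                                 name_class = cls, stringsAsFactors = FALSE))
  }
  n_hom <- round(params$homonym_frac * length(non_root))
  if (n_hom > 0 && length(non_root) >= 2) {
    a <- sample(non_root, n_hom, replace = TRUE)
    b <- sample(non_root, n_hom, replace = TRUE)
    ok <- a != b
    if (any(ok)) {
      rec <- rbind(rec, data.frame(taxon_id = ids[b[ok]],
                                   name = names_vec[a[ok]],
                                   name_class = "synonym",
                                   stringsAsFactors = FALSE))
    }
  }
  rec <- rec[!duplicated(rec), ]

  names_path <- file.path(dir, "names.dmp")
  nodes_path <- file.path(dir, "nodes.dmp")
  write_names_dump(rec, names_path)
  tree <- taxonomy_tree(ids, parents, ranks)
  write_nodes_dump(tree, nodes_path)

  structure(list(seed = seed, params = params, taxa = taxa,
                 name_records = rec, env_node = env_node,
                 names_path = names_path, nodes_path = nodes_path),
            class = "fixture_manifest")
}

# lineage names root-exclusive, highest rank first, ending at taxon
lineage_names <- function(manifest, taxon_id) {
  nm <- stats::setNames(manifest$taxa$name,
                        as.character(manifest$taxa$taxon_id))
  pr <- stats::setNames(manifest$taxa$parent_id,
                        as.character(manifest$taxa$taxon_id))
  path <- character(0)
  cur <- taxon_id
  while (cur != 1L) {
    path <- c(nm[[as.character(cur)]], path)
    cur <- pr[[as.character(cur)]]
  }
  path
}

#' Generate a synthetic SILVA export for a fixture taxonomy
#'
#' Each accession's taxonomic path is its true taxon's name lineage. A
#' stated fraction of entries get a blocked full name ("uncultured <parent
#' name>") so mapping must climb the path; another fraction get case-mangled
#' full names to exercise the capitalization retry; another fraction are
#' made unresolvable everywhere (expected to stay unmapped). The manifest
#' gains an `accessions` table recording the true source taxon and the
#' taxon the mapping algorithm is expected to produce.
#'
#' @param manifest a `fixture_manifest` from [generate_taxonomy()].
#' @param params a [fixture_params()] object.
#' @param seed integer seed.
#' @return the manifest, augmented with `accessions` (data.frame accession,
#'   taxon_id, expected_map_id, category) and `silva_path`.
#' @export
generate_silva_export <- function(manifest, params = manifest$params,
                                  seed = manifest$seed) {
  set.seed(fixture_seed(seed, "silva"))
  taxa <- manifest$taxa
  parent_of <- stats::setNames(taxa$parent_id, as.character(taxa$taxon_id))
  name_of <- stats::setNames(taxa$name, as.character(taxa$taxon_id))
  # sequences come from concrete organisms: species/genus nodes, plus the
  # environmental-samples node if present
  leafish <- taxa$taxon_id[taxa$rank %in% c("species", "genus")]
  nA <- params$n_accessions
  acc <- sprintf("FX%06d", seq_len(nA))
  category <- sample(c("plain", "blocked", "mangled", "unmappable"), nA,
                     replace = TRUE,
                     prob = c(1 - params$blocked_frac - params$mangled_frac -
                                params$unmappable_frac,
                              params$blocked_frac, params$mangled_frac,
                              params$unmappable_frac))
  src <- leafish[sample.int(length(leafish), nA, replace = TRUE)]
  # route a few blocked accessions through the environmental-samples node
  if (!is.na(manifest$env_node)) {
    is_blocked <- which(category == "blocked")
    n_env <- min(length(is_blocked), max(1L, round(0.1 * length(is_blocked))))
    if (n_env > 0) src[is_blocked[seq_len(n_env)]] <- manifest$env_node
  }

  entries <- vector("list", nA)
  expected <- integer(nA)
  for (i in seq_len(nA)) {
    tid <- src[i]
    path <- lineage_names(manifest, tid)
    full <- name_of[[as.character(tid)]]
    expect <- tid
    if (category[i] == "blocked") {
      parent_name <- name_of[[as.character(parent_of[[as.character(tid)]])]]
      full <- paste(sample(c("uncultured", "unidentified"), 1),
                    tolower(parent_name))
      # path climb lands on the deepest non-blocked path element
      if (!is.na(manifest$env_node) && tid == manifest$env_node) {
        expect <- parent_of[[as.character(tid)]]
      }
    } else if (category[i] == "mangled") {
      full <- tolower(full)
    } else if (category[i] == "unmappable") {
      full <- "unknown organism"
      path <- c(sprintf("Zzunknown lineage %d", i),
                sprintf("Zzunknown clade %d", i))
      expect <- NA_integer_
    }
    entries[[i]] <- silva_entry(acc[i], path, full)
    expected[i] <- expect
  }
  silva_path <- file.path(dirname(manifest$names_path), "silva_export.txt")
  write_silva_export(entries, silva_path)
  manifest$accessions <- data.frame(accession = acc, taxon_id = src,
                                    expected_map_id = expected,
                                    category = category,
                                    stringsAsFactors = FALSE)
  manifest$silva_path <- silva_path
  manifest
}

#' Generate a synthetic BLAST tabular file for a fixture
#'
#' Each simulated read hits its true source accession with the top bit
#' score. A stated fraction of reads score entirely below the Min Score
#' default (intended status unassigned-low-score); reads drawn from
#' unresolvable accessions are intended to end up unmapped; a fraction of
#' the remaining reads receive decoy hits to other accessions at lower
#' scores. The manifest gains a `reads` table with every intended outcome.
#'
#' @param manifest a `fixture_manifest` from [generate_silva_export()].
#' @param params a [fixture_params()] object.
#' @param seed integer seed.
#' @return the manifest, augmented with `reads` (data.frame read_id,
#'   accession, true_taxon, intended_status) and `blast_path`.
#' @export
generate_blast_tabular <- function(manifest, params = manifest$params,
                                   seed = manifest$seed) {
  stopifnot(!is.null(manifest$accessions))
  set.seed(fixture_seed(seed, "blast"))
  accs <- manifest$accessions
  mappable <- accs$accession[!is.na(accs$expected_map_id)]
  nR <- params$n_reads
  read_id <- sprintf("read%06d", seq_len(nR))
  pick <- sample.int(nrow(accs), nR, replace = TRUE)
  low <- stats::runif(nR) < params$lowscore_frac
  intended <- ifelse(low, "unassigned-low-score",
                     ifelse(is.na(accs$expected_map_id[pick]),
                            "unmapped-accession", "assigned"))
  sr <- params$score_range; lr <- params$lowscore_range

  fmt_hit <- function(q, s, score) {
    len <- sample(250:500, 1)
    pid <- stats::runif(1, 90, 100)
    mism <- sample(0:10, 1)
    sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.1e\t%.1f",
            q, s, pid, len, mism, sample(0:2, 1), 1L, len, 1L, len,
            10^-stats::runif(1, 20, 80), score)
  }

  lines <- character(0)
  for (i in seq_len(nR)) {
    a <- accs$accession[pick[i]]
    if (intended[i] == "unassigned-low-score") {
      n_hits <- sample(1:3, 1)
      for (k in seq_len(n_hits)) {
        other <- accs$accession[sample.int(nrow(accs), 1)]
        lines <- c(lines, fmt_hit(read_id[i], if (k == 1) a else other,
                                  round(stats::runif(1, lr[1], lr[2]), 1)))
      }
    } else {
      best <- round(stats::runif(1, sr[1], sr[2]), 1)
      lines <- c(lines, fmt_hit(read_id[i], a, best))
      if (intended[i] == "assigned" && stats::runif(1) < params$decoy_frac &&
          length(mappable) > 1) {
        for (k in seq_len(sample(1:2, 1))) {
          decoy <- sample(setdiff(mappable, a), 1)
          dscore <- round(stats::runif(1, 0.80, 0.95) * best, 1)
          lines <- c(lines, fmt_hit(read_id[i], decoy, max(dscore, 120.5)))
        }
      }
    }
  }
  blast_path <- file.path(dirname(manifest$names_path), "blast_hits.tsv")
  writeLines(lines, blast_path)
  manifest$reads <- data.frame(read_id = read_id,
                               accession = accs$accession[pick],
                               true_taxon = accs$expected_map_id[pick],
                               intended_status = intended,
                               stringsAsFactors = FALSE)
  manifest$blast_path <- blast_path
  manifest
}

#' Generate the full fixture set in one call
#'
#' Runs [generate_taxonomy()], [generate_silva_export()] and
#' [generate_blast_tabular()] with streams derived from one seed, and writes
#' the manifest tables as TSV next to the data files.
#'
#' @param dir output directory.
#' @param params a [fixture_params()] object.
#' @param seed integer seed.
#' @return the complete `fixture_manifest`.
#' @export
generate_fixtures <- function(dir, params = fixture_params(), seed = 42L) {
  manifest <- generate_taxonomy(dir, params, seed)
  manifest <- generate_silva_export(manifest, params, seed)
  manifest <- generate_blast_tabular(manifest, params, seed)
  utils::write.table(manifest$taxa, file.path(dir, "manifest_taxa.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(manifest$accessions,
                     file.path(dir, "manifest_accessions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(manifest$reads, file.path(dir, "manifest_reads.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}
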